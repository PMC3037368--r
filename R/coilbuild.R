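# Side-chain tip pseudo-atom lengths (CA->tip distance, Angstroem). The
# reduced representation replaces full side chains by a single pseudo-atom
# whose distance from CA scales with side-chain reach; alanine's tip is its
# CB. Glycine carries no side-chain atoms.
TIP_LENGTHS <- c(ASP = 3.7, GLU = 5.0, LYS = 6.4, ARG = 7.3, HIS = 4.6,
                 LEU = 3.9, ALA = 1.5)
TIP_DEFAULT <- 2.4
CB_LENGTH <- 1.53

tip_length <- function(res3) {
  out <- TIP_LENGTHS[res3]
  out[is.na(out)] <- TIP_DEFAULT
  unname(out)
}

#' Helix and dimer geometry parameters
#'
#' Canonical alpha-helix / coiled-coil values. `twist_per_residue` of 100
#' degrees is the isolated-helix value (3.6 residues/turn);
#' [coiled_coil_params()] uses 720/7 degrees (3.5 residues/turn), the
#' straightened average of a supercoiled helix, which keeps heptad positions
#' azimuthally aligned along the chain so that dimer interface stripes face
#' each other over arbitrarily many heptads.
#'
#' @param rise_per_residue Angstroem per residue along the axis.
#' @param twist_per_residue degrees per residue (0, 180).
#' @param helix_radius CA radius, Angstroem.
#' @param superhelix_radius,superhelix_pitch Crick supercoil descriptors,
#'   Angstroem (carried as metadata for the straightened build).
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param interhelical_offset axis-to-axis distance in a dimer, Angstroem.
#' @return object of class `helix_params`.
#' @export
helix_params <- function(rise_per_residue = 1.5, twist_per_residue = 100,
                         helix_radius = 2.3, superhelix_radius = 4.9,
                         superhelix_pitch = 148,
                         orientation = c("parallel", "antiparallel"),
                         interhelical_offset = 9.8) {
  orientation <- match.arg(orientation)
  stopifnot(rise_per_residue > 0, helix_radius > 0, superhelix_radius > 0,
            superhelix_pitch > 0, interhelical_offset > 0,
            twist_per_residue > 0, twist_per_residue < 180)
  structure(list(rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 helix_radius = helix_radius,
                 superhelix_radius = superhelix_radius,
                 superhelix_pitch = superhelix_pitch,
                 orientation = orientation,
                 interhelical_offset = interhelical_offset),
            class = "helix_params")
}

#' @rdname helix_params
#' @param ... overrides passed to [helix_params()].
#' @export
coiled_coil_params <- function(...) {
  args <- list(...)
  if (is.null(args$twist_per_residue)) args$twist_per_residue <- 720 / 7
  do.call(helix_params, args)
}

# Backbone atom placement in cylindrical coordinates relative to each CA:
# (radius, azimuth offset in deg, axial offset in A). Frozen so that bond
# geometry is plausible (N-CA ~1.4, C-N(+1) ~1.3, C-O ~1.2 A) for the
# default helix parameters; side chains point outward with a slight
# N-terminal tilt.
BB_GEOM <- list(N = c(1.55, +28, -0.75),
                C = c(1.65, -28, +0.75),
                O = c(2.00, -33, +1.90))
TIP_DIR <- c(radial = 0.83, tangential = 0.33, axial = -0.45)
TIP_DIR <- TIP_DIR / sqrt(sum(TIP_DIR^2))  # exact unit vector

#' Build an ideal reduced-atom alpha helix
#'
#' Places N, CA, C, O backbone atoms per residue on an ideal helix with axis
#' along +z, plus CB and a side-chain `TIP` pseudo-atom along the CA->CB
#' direction at a residue-type-dependent length (glycine: backbone only).
#' Deterministic.
#'
#' @param sequence one-letter amino-acid string.
#' @param params a [helix_params()].
#' @param chain chain identifier.
#' @param phi0 azimuth (degrees) of the first CA; residue k sits at
#'   `phi0 - k * twist` (clockwise as viewed from the N-terminus at -z).
#' @param start_resno residue number of the first residue.
#' @param origin length-3 offset added to all coordinates.
#' @return a [structure3d()] with charges/radii assigned by
#'   [assign_reduced_params()].
#' @export
build_ideal_helix <- function(sequence, params = helix_params(), chain = "A",
                              phi0 = 0, start_resno = 1L, origin = c(0, 0, 0)) {
  if (!nzchar(sequence)) stop("sequence must be nonempty")
  res1 <- strsplit(sequence, "")[[1]]
  res3 <- aa_1to3(res1)                 # errors on unknown codes
  n <- length(res3)
  rows <- vector("list", n)
  for (k in seq_len(n) - 1L) {
    th <- (phi0 - k * params$twist_per_residue) * pi / 180
    z <- k * params$rise_per_residue
    r <- params$helix_radius
    ca <- c(r * cos(th), r * sin(th), z)
    place <- function(g) {
      a <- th + g[2] * pi / 180
      c(g[1] * cos(a), g[1] * sin(a), z + g[3])
    }
    xyz <- rbind(N = place(BB_GEOM$N), CA = ca,
                 C = place(BB_GEOM$C), O = place(BB_GEOM$O))
    rn <- res3[k + 1L]
    if (rn != "GLY") {
      u <- c(cos(th) * TIP_DIR[["radial"]] - sin(th) * TIP_DIR[["tangential"]],
             sin(th) * TIP_DIR[["radial"]] + cos(th) * TIP_DIR[["tangential"]],
             TIP_DIR[["axial"]])
      xyz <- rbind(xyz, CB = ca + u * CB_LENGTH, TIP = ca + u * tip_length(rn))
    }
    elety <- rownames(xyz)
    rows[[k + 1L]] <- data.frame(
      chain = chain, resno = start_resno + k, resid = rn, elety = elety,
      element = ifelse(elety == "TIP", tip_element(rn),
                       ifelse(elety %in% c("N", "O"), elety, "C")),
      x = xyz[, 1] + origin[1], y = xyz[, 2] + origin[2], z = xyz[, 3] + origin[3],
      charge = 0, radius = 0, stringsAsFactors = FALSE)
  }
  out <- structure3d(do.call(rbind, rows))
  out <- assign_reduced_params(out)
  attr(out, "helix") <- list(params = params, phi0 = phi0,
                             start_resno = start_resno)
  out
}

#' Threading map
#'
#' One-to-one correspondence between a query-sequence span and a
#' template-structure span of equal length, with an integer register
#' `offset` relative to the native alignment. Under the default core-at-'d'
#' convention an offset of -1 lands the conserved core at 'c' and an offset
#' of -3 (the "shift by three" presentation) at 'a'.
#'
#' @param query_span,template_span integer `c(start, end)`, 1-based inclusive.
#' @param offset register shift relative to native.
#' @return object of class `threading_map`.
#' @export
threading_map <- function(query_span, template_span, offset = 0L) {
  stopifnot(length(query_span) == 2L, length(template_span) == 2L)
  if (diff(query_span) != diff(template_span))
    stop("query_span and template_span must have equal length (",
         diff(query_span) + 1L, " vs ", diff(template_span) + 1L, " residues)")
  structure(list(query_span = as.integer(query_span),
                 template_span = as.integer(template_span),
                 offset = as.integer(offset)),
            class = "threading_map")
}

#' Register letter of the conserved core after a register shift
#'
#' @param offset integer register shift relative to native (core at 'd').
#' @return a single letter in a--g.
#' @examples
#' register_letter(0)   # "d"
#' register_letter(-1)  # "c"  (shift-by-one variant)
#' register_letter(-3)  # "a"  (shift-by-three variant)
#' @export
register_letter <- function(offset) HEPTAD_LETTERS[((3L + offset) %% 7L) + 1L]

#' Thread a query sequence onto a template backbone
#'
#' Keeps the template backbone coordinates bit-for-bit, renames residues to
#' the query residues and rebuilds CB/TIP pseudo-atoms for the new residue
#' type along the template's side-chain direction. Applied to every chain of
#' the template (a homodimeric template is threaded on both chains).
#' Residues outside `template_span` are dropped; output residues are
#' renumbered to query numbering.
#'
#' @param query a [protein_record].
#' @param template a [structure3d()] (e.g. from [build_ideal_helix()]).
#' @param map a [threading_map()].
#' @return a [structure3d()] with a `threading` attribute carrying the map
#'   and the core register letter implied by `map$offset`.
#' @export
thread_sequence <- function(query, template, map) {
  stopifnot(inherits(map, "threading_map"))
  check_span(query, map$query_span)
  qres3 <- aa_1to3(seq_chars(query)[map$query_span[1]:map$query_span[2]])
  tpos <- map$template_span[1]:map$template_span[2]
  out <- list()
  for (ch in chain_ids(template)) {
    a <- template$atoms[template$atoms$chain == ch, , drop = FALSE]
    if (!all(tpos %in% a$resno))
      stop("template chain ", ch, " does not cover template_span")
    for (i in seq_along(tpos)) {
      res <- a[a$resno == tpos[i], , drop = FALSE]
      newname <- qres3[i]
      bb <- res[res$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
      ca <- as.numeric(bb[bb$elety == "CA", c("x", "y", "z")])
      # side-chain direction: template CB if present, else N/C bisector
      cbrow <- res[res$elety == "CB", , drop = FALSE]
      if (nrow(cbrow) == 1L) {
        u <- as.numeric(cbrow[, c("x", "y", "z")]) - ca
      } else {
        nn <- as.numeric(bb[bb$elety == "N", c("x", "y", "z")])
        cc <- as.numeric(bb[bb$elety == "C", c("x", "y", "z")])
        u <- (ca - nn) / sqrt(sum((ca - nn)^2)) + (ca - cc) / sqrt(sum((ca - cc)^2))
      }
      u <- u / sqrt(sum(u^2))
      bb$resid <- newname
      bb$resno <- map$query_span[1] + i - 1L
      newrows <- bb
      if (newname != "GLY") {
        sc <- data.frame(chain = ch, resno = bb$resno[1], resid = newname,
                         elety = c("CB", "TIP"),
                         element = c("C", tip_element(newname)),
                         x = ca[1] + u[1] * c(CB_LENGTH, tip_length(newname)),
                         y = ca[2] + u[2] * c(CB_LENGTH, tip_length(newname)),
                         z = ca[3] + u[3] * c(CB_LENGTH, tip_length(newname)),
                         charge = 0, radius = 0, stringsAsFactors = FALSE)
        newrows <- rbind(bb, sc)
      }
      out[[length(out) + 1L]] <- newrows
    }
  }
  res <- assign_reduced_params(structure3d(do.call(rbind, out)))
  attr(res, "threading") <- list(map = map, core_letter = register_letter(map$offset))
  res
}

#' Assemble a two-chain coiled-coil dimer
#'
#' Places two single-chain helices with parallel axes separated by
#' `interhelical_offset` along x. Chain B is rotated by 180 degrees about
#' the axis direction (z), which makes the interface stripes of the two
#' helices face each other: with monomers built so their core 'd' stripe
#' points along +x (see [build_zipper_monomer()]), chain A's acidic 'g'
#' tips end up adjacent to chain B's basic 'a' tips and vice versa. In
#' antiparallel mode chain B is instead rotated by 180 degrees about the y
#' axis (perpendicular to both the helix axis and the interhelical vector),
#' which reverses its N->C direction; for this charge architecture that
#' turns the charged stripe away from the interface.
#'
#' @param monomerA,monomerB single-chain [structure3d()] helices built at a
#'   common origin with axis +z.
#' @param params a [helix_params()]; `orientation` and
#'   `interhelical_offset` are used.
#' @return a two-chain [structure3d()].
#' @export
build_dimer <- function(monomerA, monomerB, params = coiled_coil_params()) {
  stopifnot(length(chain_ids(monomerA)) == 1L, length(chain_ids(monomerB)) == 1L)
  a <- monomerA$atoms
  b <- monomerB$atoms
  a$chain <- "A"
  b$chain <- "B"
  B <- structure3d(b)
  if (params$orientation == "parallel") {
    rot <- diag(c(-1, -1, 1))                       # 180 deg about z
    B <- transform_structure(B, rot, c(params$interhelical_offset, 0, 0))
  } else {
    zc <- mean(range(b$z))
    rot <- diag(c(-1, 1, -1))                       # 180 deg about y
    B <- transform_structure(B, rot, c(params$interhelical_offset, 0, 2 * zc))
  }
  out <- structure3d(rbind(a, B$atoms))
  attr(out, "dimer") <- list(params = params)
  out
}

#' Build a zipper monomer with its core stripe facing +x
#'
#' Convenience wrapper around [build_ideal_helix()] that sets the initial
#' azimuth so the conserved-core track (first core residue at sequence
#' position `core_start` within `sequence`) points along +x, optionally
#' rotated by a register shift of `register_shift` positions
#' (`core letter = register_letter(-register_shift)`).
#'
#' @param sequence one-letter string.
#' @param core_start 1-based position of the first core residue in
#'   `sequence`.
#' @param params a [helix_params()].
#' @param register_shift non-negative integer register shift (0 native,
#'   1 core at 'c', 3 core at 'a').
#' @param chain chain id.
#' @return a [structure3d()].
#' @export
build_zipper_monomer <- function(sequence, core_start = 1L,
                                 params = coiled_coil_params(),
                                 register_shift = 0L, chain = "A") {
  phi0 <- ((core_start - 1L) - register_shift) * params$twist_per_residue
  build_ideal_helix(sequence, params, chain = chain, phi0 = phi0)
}

#' Swap core residues in a structure
#'
#' Renames residues at `positions` from `from_res` to `to_res` (applied on
#' every chain) and rebuilds the side-chain tip pseudo-atom for the new
#' residue type. Backbone coordinates are untouched.
#'
#' @param structure a [structure3d()].
#' @param from_res,to_res residue codes (1- or 3-letter).
#' @param positions residue numbers to mutate.
#' @return mutated [structure3d()].
#' @export
mutate_core <- function(structure, from_res, to_res, positions) {
  norm3 <- function(r) if (nchar(r) == 1L) aa_1to3(r) else toupper(r)
  from3 <- norm3(from_res); to3 <- norm3(to_res)
  if (length(positions) == 0L) return(structure)
  a <- structure$atoms
  for (ch in chain_ids(structure)) {
    have <- unique(a$resno[a$chain == ch])
    missing <- setdiff(positions, have)
    if (length(missing))
      stop("positions absent from chain ", ch, ": ", paste(missing, collapse = ","))
    carried <- vapply(positions, function(p)
      a$resid[a$chain == ch & a$resno == p][1], "")
    if (!all(carried == from3))
      stop("position(s) ", paste(positions[carried != from3], collapse = ","),
           " in chain ", ch, " do not carry ", from3)
  }
  sel <- a$chain %in% chain_ids(structure) & a$resno %in% positions
  keep <- !(sel & a$elety %in% c("CB", "TIP"))
  newrows <- list()
  if (to3 != "GLY") {
    for (ch in chain_ids(structure)) for (p in positions) {
      res <- a[a$chain == ch & a$resno == p, , drop = FALSE]
      ca <- as.numeric(res[res$elety == "CA", c("x", "y", "z")])
      cbrow <- res[res$elety == "CB", , drop = FALSE]
      if (nrow(cbrow) == 1L) {
        u <- as.numeric(cbrow[, c("x", "y", "z")]) - ca
      } else {
        nn <- as.numeric(res[res$elety == "N", c("x", "y", "z")])
        cc <- as.numeric(res[res$elety == "C", c("x", "y", "z")])
        u <- (ca - nn) / sqrt(sum((ca - nn)^2)) + (ca - cc) / sqrt(sum((ca - cc)^2))
      }
      u <- u / sqrt(sum(u^2))
      newrows[[length(newrows) + 1L]] <- data.frame(
        chain = ch, resno = p, resid = to3, elety = c("CB", "TIP"),
        element = c("C", tip_element(to3)),
        x = ca[1] + u[1] * c(CB_LENGTH, tip_length(to3)),
        y = ca[2] + u[2] * c(CB_LENGTH, tip_length(to3)),
        z = ca[3] + u[3] * c(CB_LENGTH, tip_length(to3)),
        charge = 0, radius = 0, stringsAsFactors = FALSE)
    }
  }
  a$resid[sel] <- to3
  a <- a[keep, , drop = FALSE]
  a <- rbind(a, do.call(rbind, newrows))
  a <- a[order(match(a$chain, chain_ids(structure)), a$resno,
               match(a$elety, c("N", "CA", "C", "O", "CB", "TIP"))), ,
         drop = FALSE]
  assign_reduced_params(structure3d(a))
}

#' Optimal rigid superposition and RMSD
#'
#' Least-squares (Kabsch) superposition of `B` onto `A` over the selected
#' atoms, reflections excluded (proper rotations only).
#'
#' @param A,B [structure3d()] objects with equal atom counts after selection.
#' @param atom_selection `"backbone"` (N, CA, C, O), `"CA"`, or `"all"`.
#' @return list with `rmsd` (Angstroem), `rotation`, `translation` (mapping
#'   selected B coordinates onto A), and `fitted` (transformed B coordinate
#'   matrix).
#' @export
superpose_and_rmsd <- function(A, B, atom_selection = c("backbone", "CA", "all")) {
  atom_selection <- match.arg(atom_selection)
  sel <- function(x) switch(atom_selection,
    backbone = backbone_sel(x),
    CA = x$atoms$elety == "CA",
    all = rep(TRUE, nrow(x$atoms)))
  P <- xyz_matrix(A, sel(A))
  Q <- xyz_matrix(B, sel(B))
  if (nrow(P) != nrow(Q))
    stop("selection yields different atom counts (", nrow(P), " vs ", nrow(Q), ")")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(Q0, P0))            # 3x3: t(Q0) %*% P0
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- sweep(Q0 %*% t(R), 2, cp, "+")
  rmsd <- sqrt(mean(rowSums((fitted - P)^2)))
  list(rmsd = rmsd, rotation = R, translation = cp - as.numeric(R %*% cq),
       fitted = fitted)
}

# Soft-sphere overlap energy of tip pseudo-atoms against all atoms of other
# residues: sum over pairs with r < r_i + r_j of (r_i + r_j - r)^2.
tip_overlap_energy <- function(tipxyz, tiprad, tipkey, xyz, rad, key) {
  E <- 0
  for (i in seq_len(nrow(tipxyz))) {
    ok <- key != tipkey[i]
    d2 <- colSums((t(xyz[ok, , drop = FALSE]) - tipxyz[i, ])^2)
    d0 <- tiprad[i] + rad[ok]
    ov <- d2 < d0^2
    if (any(ov)) E <- E + sum((d0[ov] - sqrt(d2[ov]))^2)
  }
  E
}

#' Relax side-chain tip positions
#'
#' Greedy gradient reduction of a soft-sphere steric overlap energy on the
#' tip pseudo-atoms. The backbone (and CB) is frozen; each tip is moved
#' against the overlap gradient and re-projected onto its fixed CA-tip
#' distance. Steps that do not decrease the energy are rejected (with step
#' halving), so the energy trace is non-increasing. Deterministic.
#'
#' @param structure a [structure3d()].
#' @param n_steps number of gradient steps (>= 0).
#' @param step_size initial step, Angstroem.
#' @return relaxed [structure3d()] with attribute `relax_trace` (energy
#'   after each accepted/attempted step, starting at the input energy).
#' @export
relax_sidechains <- function(structure, n_steps = 200L, step_size = 0.05) {
  stopifnot(n_steps >= 0L)
  if (n_steps == 0L) return(structure)
  a <- structure$atoms
  key <- paste(a$chain, a$resno)
  tips <- which(a$elety == "TIP")
  if (length(tips) == 0L) return(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$radius
  ca_idx <- vapply(tips, function(i)
    which(a$chain == a$chain[i] & a$resno == a$resno[i] & a$elety == "CA"), 0L)
  lens <- sqrt(rowSums((xyz[tips, , drop = FALSE] - xyz[ca_idx, , drop = FALSE])^2))
  energy <- function(m) tip_overlap_energy(m[tips, , drop = FALSE], rad[tips],
                                           key[tips], m, rad, key)
  E <- energy(xyz)
  trace <- E
  h <- step_size
  for (step in seq_len(n_steps)) {
    if (E == 0) { trace <- c(trace, rep(E, n_steps - step + 1L)); break }
    grad <- matrix(0, length(tips), 3)
    for (t in seq_along(tips)) {
      i <- tips[t]
      ok <- key != key[i]
      dv <- sweep(xyz[ok, , drop = FALSE], 2, xyz[i, ], "-")
      d <- sqrt(rowSums(dv^2))
      d0 <- rad[i] + rad[ok]
      ov <- d < d0 & d > 0
      # dE/dx_tip = sum 2*(d0-d) * (x_j - x_tip)/d  (moving toward x_j
      # deepens the overlap), with dv = x_j - x_tip
      if (any(ov))
        grad[t, ] <- colSums(2 * (d0[ov] - d[ov]) / d[ov] * dv[ov, , drop = FALSE])
    }
    trial <- xyz
    trial[tips, ] <- xyz[tips, , drop = FALSE] - h * grad
    # re-project onto the CA-tip sphere
    v <- trial[tips, , drop = FALSE] - xyz[ca_idx, , drop = FALSE]
    v <- v / sqrt(rowSums(v^2)) * lens
    trial[tips, ] <- xyz[ca_idx, , drop = FALSE] + v
    Enew <- energy(trial)
    if (Enew <= E) {
      xyz <- trial
      E <- Enew
    } else {
      h <- h / 2
    }
    trace <- c(trace, E)
  }
  a[, c("x", "y", "z")] <- xyz
  out <- structure3d(a)
  attributes(out) <- c(attributes(out), list(relax_trace = trace))
  out
}
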