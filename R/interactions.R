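# Charged-group atoms of a residue for salt-bridge detection. Reduced mode:
# the TIP pseudo-atom. Full-atom mode: the terminal N/O atoms of the charged
# group.
SALT_GROUP_ATOMS <- list(
  ASP = c("TIP", "OD1", "OD2"), GLU = c("TIP", "OE1", "OE2"),
  LYS = c("TIP", "NZ"), ARG = c("TIP", "NH1", "NH2", "NE"),
  HIS = c("TIP", "ND1", "NE2"))

salt_group_sel <- function(a) {
  sel <- rep(FALSE, nrow(a))
  for (res in names(SALT_GROUP_ATOMS))
    sel <- sel | (a$resid == res & a$elety %in% SALT_GROUP_ATOMS[[res]])
  sel
}

# Donor/acceptor heavy atoms for hydrogen bonds: backbone N and O,
# side-chain N/O of polar residues, polar TIP pseudo-atoms.
hbond_atom_sel <- function(a) {
  bb <- a$elety %in% c("N", "O")
  sc_polar <- a$element %in% c("N", "O") & !(a$elety %in% c("N", "CA", "C", "O", "CB"))
  tip <- a$elety == "TIP" & a$resid %in% POLAR_TIP3
  bb | (sc_polar & a$elety != "TIP") | tip
}

# All intermolecular atom pairs between two chains within a cutoff,
# reduced to one row per residue pair at the minimum distance.
min_residue_pairs <- function(a, selA, selB, cutoff) {
  ia <- which(selA); ib <- which(selB)
  if (length(ia) == 0L || length(ib) == 0L)
    return(data.frame())
  A <- as.matrix(a[ia, c("x", "y", "z")])
  B <- as.matrix(a[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(data.frame())
  df <- data.frame(
    chainA = a$chain[ia[hit[, 1]]], resA = a$resid[ia[hit[, 1]]],
    resnoA = a$resno[ia[hit[, 1]]],
    chainB = a$chain[ib[hit[, 2]]], resB = a$resid[ib[hit[, 2]]],
    resnoB = a$resno[ib[hit[, 2]]],
    distance = sqrt(d2[hit]), stringsAsFactors = FALSE)
  key <- paste(df$resnoA, df$resnoB)
  df <- df[order(key, df$distance), , drop = FALSE]
  df <- df[!duplicated(paste(df$resnoA, df$resnoB)), , drop = FALSE]
  df[order(df$resnoA, df$resnoB), , drop = FALSE]
}

chain_pair_or_warn <- function(structure) {
  ch <- chain_ids(structure)
  if (length(ch) < 2L) {
    warning("structure has a single chain; no intermolecular contacts")
    return(NULL)
  }
  ch[1:2]
}

empty_contacts <- function() {
  data.frame(chainA = character(), resA = character(), resnoA = integer(),
             chainB = character(), resB = character(), resnoB = integer(),
             type = character(), distance = numeric(), stringsAsFactors = FALSE)
}

#' Detect intermolecular salt bridges
#'
#' A salt bridge is an acidic residue (Asp/Glu) of one chain and a basic
#' residue (Lys/Arg/His) of the other whose charged-group atoms approach
#' within `cutoff` (default 4.0 Angstroem, the common literature criterion).
#' Each residue pair is reported once, at its minimum group-group distance.
#' In the reduced representation the charged group is the side-chain TIP
#' pseudo-atom; in full-atom structures the terminal N/O atoms are used.
#'
#' @param structure a [structure3d()] with at least two chains.
#' @param cutoff Angstroem.
#' @return data frame of contacts (`chainA`, `resA`, `resnoA`, `chainB`,
#'   `resB`, `resnoB`, `type`, `distance`); empty with a warning on
#'   single-chain input.
#' @export
detect_salt_bridges <- function(structure, cutoff = 4.0) {
  ch <- chain_pair_or_warn(structure)
  if (is.null(ch)) return(empty_contacts())
  a <- structure$atoms
  grp <- salt_group_sel(a)
  acidic <- grp & a$resid %in% ACIDIC3
  basic <- grp & a$resid %in% BASIC3
  out <- rbind(
    min_residue_pairs(a, acidic & a$chain == ch[1], basic & a$chain == ch[2], cutoff),
    min_residue_pairs(a, basic & a$chain == ch[1], acidic & a$chain == ch[2], cutoff))
  if (nrow(out) == 0L) return(empty_contacts())
  out$type <- "salt_bridge"
  out <- out[order(out$resnoA, out$resnoB), , drop = FALSE]
  rownames(out) <- NULL
  out[, names(empty_contacts())]
}

#' Detect intermolecular hydrogen bonds
#'
#' Donor/acceptor heavy atoms (backbone N and O, side-chain N/O of polar
#' residues, and polar TIP pseudo-atoms) of different chains within
#' `heavy_cutoff` are reported as hydrogen bonds; a pair must involve at
#' least one oxygen (N-N pairs are not counted). Reduced models carry no
#' hydrogens, so the donor-H...acceptor angle criterion (`angle_min`) is
#' applied only when explicit hydrogens are present in the input.
#'
#' @param structure a [structure3d()] with at least two chains.
#' @param heavy_cutoff donor-acceptor heavy-atom distance cutoff, Angstroem.
#' @param angle_min minimal D-H...A angle in degrees (full-atom mode only).
#' @return contact data frame as in [detect_salt_bridges()].
#' @export
detect_hbonds <- function(structure, heavy_cutoff = 3.5, angle_min = 120) {
  ch <- chain_pair_or_warn(structure)
  if (is.null(ch)) return(empty_contacts())
  a <- structure$atoms
  pol <- hbond_atom_sel(a)
  ia <- which(pol & a$chain == ch[1])
  ib <- which(pol & a$chain == ch[2])
  if (length(ia) == 0L || length(ib) == 0L) return(empty_contacts())
  A <- as.matrix(a[ia, c("x", "y", "z")])
  B <- as.matrix(a[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= heavy_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_contacts())
  elA <- a$element[ia[hit[, 1]]]
  elB <- a$element[ib[hit[, 2]]]
  keep <- elA == "O" | elB == "O"       # at least one acceptor oxygen
  hit <- hit[keep, , drop = FALSE]
  if (nrow(hit) == 0L) return(empty_contacts())
  has_h <- any(a$element == "H" | grepl("^H", a$elety))
  if (has_h) {
    keep2 <- vapply(seq_len(nrow(hit)), function(k) {
      i <- ia[hit[k, 1]]; j <- ib[hit[k, 2]]
      hbond_angle_ok(a, i, j, angle_min) || hbond_angle_ok(a, j, i, angle_min)
    }, logical(1))
    hit <- hit[keep2, , drop = FALSE]
    if (nrow(hit) == 0L) return(empty_contacts())
  }
  df <- data.frame(
    chainA = a$chain[ia[hit[, 1]]], resA = a$resid[ia[hit[, 1]]],
    resnoA = a$resno[ia[hit[, 1]]],
    chainB = a$chain[ib[hit[, 2]]], resB = a$resid[ib[hit[, 2]]],
    resnoB = a$resno[ib[hit[, 2]]],
    distance = sqrt(d2[cbind(hit[, 1], hit[, 2])]), stringsAsFactors = FALSE)
  df <- df[order(paste(df$resnoA, df$resnoB), df$distance), , drop = FALSE]
  df <- df[!duplicated(paste(df$resnoA, df$resnoB)), , drop = FALSE]
  df$type <- "hydrogen_bond"
  df <- df[order(df$resnoA, df$resnoB), , drop = FALSE]
  rownames(df) <- NULL
  df[, names(empty_contacts())]
}

# donor i (N) with an attached hydrogen, acceptor j: D-H...A angle >= min.
hbond_angle_ok <- function(a, i, j, angle_min) {
  if (a$element[i] != "N") return(FALSE)
  same <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
                (a$element == "H" | grepl("^H", a$elety)))
  if (length(same) == 0L) return(TRUE)   # donor without explicit H: accept
  di <- as.numeric(a[i, c("x", "y", "z")])
  dj <- as.numeric(a[j, c("x", "y", "z")])
  for (h in same) {
    hx <- as.numeric(a[h, c("x", "y", "z")])
    if (sqrt(sum((hx - di)^2)) > 1.3) next
    v1 <- di - hx; v2 <- dj - hx
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (ang >= angle_min) return(TRUE)
  }
  FALSE
}

#' Intermolecular contact inventory of a dimer
#'
#' Merged, deduplicated residue-pair table of salt bridges and hydrogen
#' bonds between the two chains, sorted by chain-A residue index. A residue
#' pair is typed by its strongest interaction: pairs qualifying as salt
#' bridges are excluded from the hydrogen-bond list.
#'
#' @param structure a two-chain [structure3d()].
#' @param salt_cutoff,hbond_cutoff distance cutoffs, Angstroem.
#' @return object of class `contact_inventory`: list with `contacts` (data
#'   frame), `n_salt_bridges`, `n_hbonds`.
#' @export
interface_inventory <- function(structure, salt_cutoff = 4.0, hbond_cutoff = 3.5) {
  if (length(chain_ids(structure)) < 2L) {
    warning("structure has a single chain; no intermolecular contacts")
    return(structure(list(contacts = empty_contacts(), n_salt_bridges = 0L,
                          n_hbonds = 0L), class = "contact_inventory"))
  }
  sb <- detect_salt_bridges(structure, salt_cutoff)
  hb <- detect_hbonds(structure, hbond_cutoff)
  if (nrow(sb) && nrow(hb)) {
    sbkey <- paste(sb$resnoA, sb$resnoB)
    hb <- hb[!(paste(hb$resnoA, hb$resnoB) %in% sbkey), , drop = FALSE]
  }
  contacts <- rbind(sb, hb)
  if (nrow(contacts)) {
    contacts <- contacts[order(contacts$resnoA, contacts$resnoB,
                               contacts$type), , drop = FALSE]
    rownames(contacts) <- NULL
  }
  structure(list(contacts = contacts,
                 n_salt_bridges = nrow(sb),
                 n_hbonds = nrow(hb)),
            class = "contact_inventory")
}

#' @export
print.contact_inventory <- function(x, ...) {
  cat(sprintf("<contact_inventory> %d salt bridges, %d hydrogen bonds\n",
              x$n_salt_bridges, x$n_hbonds))
  invisible(x)
}

#' Contact-count ratios between two inventories
#'
#' @param invA,invB [interface_inventory()] results (A is the numerator).
#' @return list with `hbond_ratio` and `salt_ratio`; a ratio over a zero
#'   denominator is reported as `Inf`.
#' @export
inventory_ratio <- function(invA, invB) {
  rat <- function(x, y) if (y == 0) Inf else x / y
  list(hbond_ratio = rat(invA$n_hbonds, invB$n_hbonds),
       salt_ratio = rat(invA$n_salt_bridges, invB$n_salt_bridges))
}

#' Write a contact inventory TSV
#'
#' Columns: chainA_res, chainA_index, chainB_res, chainB_index, type,
#' distance_A; one `#`-prefixed header line.
#'
#' @param inventory a [interface_inventory()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(inventory, path) {
  df <- inventory$contacts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chainA_res\tchainA_index\tchainB_res\tchainB_index\ttype\tdistance_A", con)
  if (nrow(df)) {
    out <- data.frame(df$resA, df$resnoA, df$resB, df$resnoB, df$type,
                      sprintf("%.3f", df$distance))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
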