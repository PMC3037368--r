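#' Reduced-atom 3D structure
#'
#' A `structure3d` wraps a per-atom data frame with columns `chain`, `resno`
#' (1-based, strictly increasing within a chain), `resid` (3-letter code),
#' `elety` (atom name: `N`, `CA`, `C`, `O`, `CB`, `TIP`, or PDB names in
#' full-atom mode), `element`, coordinates `x`, `y`, `z` in Angstroem,
#' `charge` (e) and `radius` (Angstroem, used for sterics and SASA).
#'
#' In the reduced representation each residue carries the four backbone
#' atoms, a CB, and a single side-chain `TIP` pseudo-atom placed along the
#' CA->CB direction at a residue-type-dependent length; glycine carries
#' backbone atoms only.
#'
#' @param atoms data frame as described above.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  req <- c("chain", "resno", "resid", "elety", "element",
           "x", "y", "z", "charge", "radius")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue indices must be non-decreasing in chain ", ch)
  }
  charged <- atoms$charge != 0
  if (any(charged & !(atoms$resid %in% c(ACIDIC3, BASIC3))))
    stop("nonzero charge on a residue outside ASP/GLU/LYS/ARG/HIS")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure3d> %d chain(s) [%s], %d residues, %d atoms\n",
              length(unique(a$chain)), paste(unique(a$chain), collapse = ","),
              nrow(unique(a[, c("chain", "resno")])), nrow(a)))
  invisible(x)
}

#' @rdname structure3d
#' @param x a `structure3d`.
#' @export
chain_ids <- function(x) unique(x$atoms$chain)

#' Extract one or more chains as a new structure
#'
#' Coordinates are kept as-is (the single-trajectory convention: a monomer
#' extracted from a complex has identical coordinates).
#'
#' @param x a [structure3d()].
#' @param chains chain identifiers to keep.
#' @return a `structure3d`.
#' @export
extract_chains <- function(x, chains) {
  a <- x$atoms[x$atoms$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms in chain(s) ", paste(chains, collapse = ","))
  structure3d(a)
}

xyz_matrix <- function(x, sel = NULL) {
  a <- x$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

backbone_sel <- function(x) x$atoms$elety %in% c("N", "CA", "C", "O")

# vdW-like radii by atom class for the reduced representation.
DEFAULT_RADII <- c(N = 1.55, O = 1.52, C = 1.70, S = 1.80, TIP = 2.00)

atom_radius <- function(elety, element) {
  ifelse(elety == "TIP", DEFAULT_RADII[["TIP"]],
         ifelse(element %in% names(DEFAULT_RADII),
                DEFAULT_RADII[element], DEFAULT_RADII[["C"]]))
}

tip_element <- function(res3) {
  ifelse(res3 %in% c("ASP", "GLU", "SER", "THR", "TYR"), "O",
  ifelse(res3 %in% c("LYS", "ARG", "HIS", "ASN", "GLN", "TRP"), "N",
  ifelse(res3 == "CYS", "S", "C")))
}

# Formal charge of the side-chain tip pseudo-atom.
tip_charge <- function(res3, his_charged = FALSE) {
  ifelse(res3 %in% c("ASP", "GLU"), -1,
  ifelse(res3 %in% c("LYS", "ARG"), 1,
  ifelse(res3 == "HIS" & his_charged, 1, 0)))
}

#' Assign reduced-model charges and radii
#'
#' Formal charges of +-1e are placed on the side-chain tip pseudo-atoms of
#' Asp/Glu (negative) and Lys/Arg (positive); His is neutral unless
#' `his_charged`. Radii follow the per-class table (`TIP` 2.0, N 1.55,
#' O 1.52, C 1.70 Angstroem).
#'
#' @param x a [structure3d()].
#' @param his_charged treat histidine tips as +1e.
#' @return the structure with `charge` and `radius` columns filled.
#' @export
assign_reduced_params <- function(x, his_charged = FALSE) {
  a <- x$atoms
  a$radius <- atom_radius(a$elety, a$element)
  a$charge <- ifelse(a$elety == "TIP", tip_charge(a$resid, his_charged), 0)
  structure3d(a)
}

#' Apply a rigid transform to a structure
#'
#' @param x a [structure3d()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @param chains chains to transform (default all).
#' @return transformed `structure3d`.
#' @export
transform_structure <- function(x, rotation = diag(3), translation = c(0, 0, 0),
                                chains = NULL) {
  a <- x$atoms
  sel <- if (is.null(chains)) rep(TRUE, nrow(a)) else a$chain %in% chains
  xyz <- as.matrix(a[sel, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  a[sel, c("x", "y", "z")] <- xyz
  structure3d(a)
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM/TER/END records through bio3d, with occupancy 1.00,
#' B-factor 0.00 and the element column populated. Optional `REMARK` lines
#' (e.g. the generator seed) are prepended.
#'
#' @param x a [structure3d()].
#' @param path output path.
#' @param remarks character vector of remark texts.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(x, path, remarks = NULL) {
  a <- x$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  lines <- readLines(tmp)
  if (!is.null(remarks))
    lines <- c(sprintf("REMARK   3 %s", remarks), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure from a PDB file
#'
#' ATOM records are read through bio3d. Charges and radii are initialised
#' from the reduced-model rules for tip pseudo-atoms when present; full-atom
#' files receive per-element radii and zero charges (a per-atom charge table
#' can be applied afterwards).
#'
#' @param path PDB file path.
#' @return a [structure3d()].
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1, 1)
  elem <- trimws(elem)
  a <- data.frame(chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
                  resno = at$resno, resid = at$resid, elety = trimws(at$elety),
                  element = elem, x = at$x, y = at$y, z = at$z,
                  charge = 0, radius = 0, stringsAsFactors = FALSE)
  assign_reduced_params(structure3d(a))
}
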