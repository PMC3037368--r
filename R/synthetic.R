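# Default filler alphabet: uniform over residues that are neither possible
# core residues (A, G, L), charged (D, E, K, R, H), helix-breaking (P) nor
# part of a planted signature (C), so fillers cannot create spurious zipper,
# charge or NLS motifs. "natural" switches to background amino-acid
# frequencies over the full alphabet (hard mode).
FILLER_SET <- c("F", "I", "M", "N", "Q", "S", "T", "V", "W", "Y")

# Rounded vertebrate-like background frequencies for hard mode.
NATURAL_FREQS <- c(A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.014,
                   Q = 0.040, E = 0.067, G = 0.071, H = 0.023, I = 0.059,
                   L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
                   S = 0.066, T = 0.053, W = 0.011, Y = 0.029, V = 0.069)

filler_sampler <- function(filler_composition) {
  if (is.null(filler_composition))
    return(function(n) sample(FILLER_SET, n, replace = TRUE))
  if (identical(filler_composition, "natural"))
    return(function(n) sample(names(NATURAL_FREQS), n, replace = TRUE,
                              prob = NATURAL_FREQS))
  stopifnot(is.numeric(filler_composition), !is.null(names(filler_composition)))
  function(n) sample(names(filler_composition), n, replace = TRUE,
                     prob = filler_composition)
}

#' Synthetic zipper specification
#'
#' Describes a coiled-coil zipper segment of `n_heptads` heptads laid out
#' core-first: the core residue sits at positions 1, 8, 15, ... ('d'
#' register by default) and each heptad carries a flanking charge pair at
#' core+3 ('g') and core+4 (the following 'a'). With probability
#' `complementarity_fraction` a pair is complementary (acidic 'g', basic
#' 'a'); otherwise it is charge-scrambled: both positions get the same
#' random sign, which breaks the interhelical attraction in a homodimer.
#'
#' @param n_heptads number of heptads (>= 2).
#' @param core_residue `"A"`, `"L"` or `"G"`.
#' @param core_register `"d"` (default) or `"a"` (reported register).
#' @param complementarity_fraction fraction of complementary charge pairs
#'   in `[0, 1]`.
#' @param filler_composition `NULL` (uniform safe set), `"natural"`, or a
#'   named frequency vector.
#' @param seed integer seed.
#' @return object of class `zipper_spec`.
#' @export
zipper_spec <- function(n_heptads = 6L, core_residue = c("A", "L", "G"),
                        core_register = c("d", "a"),
                        complementarity_fraction = 1.0,
                        filler_composition = NULL, seed = 1L) {
  core_residue <- match.arg(core_residue)
  core_register <- match.arg(core_register)
  if (n_heptads < 2L) stop("n_heptads must be >= 2")
  if (complementarity_fraction < 0 || complementarity_fraction > 1)
    stop("complementarity_fraction must be in [0, 1]")
  structure(list(n_heptads = as.integer(n_heptads), core_residue = core_residue,
                 core_register = core_register,
                 complementarity_fraction = complementarity_fraction,
                 filler_composition = filler_composition, seed = as.integer(seed)),
            class = "zipper_spec")
}

# Sequence layout of a zipper segment; pure given the RNG state.
zipper_chars <- function(spec) {
  n <- spec$n_heptads
  s <- filler_sampler(spec$filler_composition)(7L * n)
  core <- 1L + 7L * (0:(n - 1L))
  s[core] <- spec$core_residue
  comp <- runif(n) < spec$complementarity_fraction
  gpos <- core + 3L
  apos <- core + 4L
  for (k in seq_len(n)) {
    if (comp[k]) {
      s[gpos[k]] <- sample(c("D", "E"), 1L)
      s[apos[k]] <- sample(c("K", "R"), 1L)
    } else {
      if (runif(1) < 0.5) {
        s[gpos[k]] <- sample(c("D", "E"), 1L)
        s[apos[k]] <- sample(c("D", "E"), 1L)
      } else {
        s[gpos[k]] <- sample(c("K", "R"), 1L)
        s[apos[k]] <- sample(c("K", "R"), 1L)
      }
    }
  }
  list(chars = s, core = core, comp = comp, gpos = gpos, apos = apos)
}

#' Generate a synthetic zipper sequence with ground truth
#'
#' Seeded and deterministic: the same spec and seed give byte-identical
#' output. The ground truth records the planted phase (whole-sequence
#' register anchor, core at 'd'), core positions and complementary pairs,
#' and is returned separately from the record so detectors cannot read it
#' from the sequence.
#'
#' @param spec a [zipper_spec()].
#' @return list with `record` (a [protein_record]) and `truth` (list with
#'   `span`, `phase`, `core_positions`, `complementary_pairs`,
#'   `n_complementary_pairs`, `seed`).
#' @export
generate_zipper <- function(spec) {
  stopifnot(inherits(spec, "zipper_spec"))
  z <- withr::with_seed(spec$seed, zipper_chars(spec))
  seqs <- paste(z$chars, collapse = "")
  rec <- protein_record(sprintf("zip_n%d_%s_s%d", spec$n_heptads,
                                spec$core_residue, spec$seed),
                        seqs,
                        annotations = list(description = sprintf("seed=%d", spec$seed)))
  truth <- list(span = c(1L, 7L * spec$n_heptads),
                phase = (3L - (z$core[1] - 1L)) %% 7L,
                core_positions = z$core,
                complementary_pairs = data.frame(g = z$gpos[z$comp],
                                                 a = z$apos[z$comp]),
                n_complementary_pairs = sum(z$comp),
                seed = spec$seed)
  list(record = rec, truth = truth)
}

#' Synthetic group II BPC-like protein specification
#'
#' Architecture of a full synthetic protein: the zipper segment near the
#' N-terminus (default: first core residue at position 41, six heptads,
#' matching the Ala41...Ala76 anchor spacing), a basic NLS region carrying
#' the three motifs KPKRxKR / KRxxK / KxKK at the canonical offsets
#' 165 / 184 / 192, and a C-terminal basic domain with five invariant
#' cysteines. The synthetic basic domain draws its basic residues from
#' Arg/His only, so the K-anchored NLS patterns cannot match outside the
#' planted motifs.
#'
#' @param zipper a [zipper_spec()].
#' @param zipper_start position of the first core residue.
#' @param nls_offsets named integer vector: start positions of `KPKRxKR`,
#'   `KRxxK`, `KxKK`.
#' @param basic_domain list with `start`, `length`, `cys_positions`
#'   (exactly 5, relative to `start`).
#' @param total_length protein length.
#' @param plant_nls plant the three motifs (disable for a scrambled
#'   negative control).
#' @param seed integer seed.
#' @return object of class `bpc_spec`.
#' @export
bpc_spec <- function(zipper = zipper_spec(), zipper_start = 41L,
                     nls_offsets = c(KPKRxKR = 165L, KRxxK = 184L, KxKK = 192L),
                     basic_domain = list(start = 211L, length = 60L,
                                         cys_positions = c(8L, 15L, 30L, 40L, 52L)),
                     total_length = 280L, plant_nls = TRUE, seed = 1L) {
  stopifnot(inherits(zipper, "zipper_spec"),
            all(c("KPKRxKR", "KRxxK", "KxKK") %in% names(nls_offsets)))
  if (length(basic_domain$cys_positions) != 5L)
    stop("basic_domain must plant exactly 5 cysteines")
  spans <- cbind(nls_offsets, nls_offsets + NLS_LENGTHS[names(nls_offsets)] - 1L)
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  if (any(spans[-1, 1] <= spans[-nrow(spans), 2]))
    stop("NLS motif offsets overlap")
  zip_end <- zipper_start + 7L * zipper$n_heptads - 1L
  if (zip_end >= min(nls_offsets)) stop("zipper overlaps the NLS region")
  if (basic_domain$start + basic_domain$length - 1L > total_length)
    stop("basic domain extends past total_length")
  if (any(basic_domain$cys_positions < 1L |
          basic_domain$cys_positions > basic_domain$length))
    stop("cys_positions must fall inside the basic domain")
  structure(list(zipper = zipper, zipper_start = as.integer(zipper_start),
                 nls_offsets = nls_offsets, basic_domain = basic_domain,
                 total_length = as.integer(total_length),
                 plant_nls = isTRUE(plant_nls), seed = as.integer(seed)),
            class = "bpc_spec")
}

#' Generate a synthetic group II BPC-like protein
#'
#' @param spec a [bpc_spec()].
#' @return list with `record` and `truth` (planted zipper, motif spans,
#'   absolute cysteine positions, domain boundaries, seed).
#' @export
generate_bpc_protein <- function(spec) {
  stopifnot(inherits(spec, "bpc_spec"))
  out <- withr::with_seed(spec$seed, {
    s <- filler_sampler(spec$zipper$filler_composition)(spec$total_length)
    z <- zipper_chars(spec$zipper)
    zi <- spec$zipper_start:(spec$zipper_start + length(z$chars) - 1L)
    s[zi] <- z$chars
    motif_truth <- list()
    if (spec$plant_nls) {
      xfill <- function(n) sample(setdiff(FILLER_SET, c("K", "R")), n, replace = TRUE)
      plant <- function(start, tmpl) {
        chars <- strsplit(tmpl, "")[[1]]
        chars[chars == "x"] <- xfill(sum(chars == "x"))
        s[start:(start + length(chars) - 1L)] <<- chars
        c(start, start + length(chars) - 1L)
      }
      motif_truth$KPKRxKR <- plant(spec$nls_offsets[["KPKRxKR"]], "KPKRxKR")
      motif_truth$KRxxK <- plant(spec$nls_offsets[["KRxxK"]], "KRxxK")
      motif_truth$KxKK <- plant(spec$nls_offsets[["KxKK"]], "KxKK")
    }
    bd <- spec$basic_domain
    bi <- bd$start:(bd$start + bd$length - 1L)
    s[bi] <- sample(c("R", "H", "S", "T"), bd$length, replace = TRUE,
                    prob = c(0.4, 0.2, 0.2, 0.2))
    cys_abs <- bd$start + bd$cys_positions - 1L
    s[cys_abs] <- "C"
    list(chars = s, z = z, motif_truth = motif_truth, cys_abs = cys_abs)
  })
  rec <- protein_record(sprintf("bpc_s%d", spec$seed),
                        paste(out$chars, collapse = ""),
                        annotations = list(description = sprintf("seed=%d", spec$seed)))
  core_abs <- spec$zipper_start + out$z$core - 1L
  truth <- list(
    zipper = list(span = c(spec$zipper_start,
                           spec$zipper_start + 7L * spec$zipper$n_heptads - 1L),
                  phase = (3L - (core_abs[1] - 1L)) %% 7L,
                  core_positions = core_abs,
                  n_complementary_pairs = sum(out$z$comp)),
    nls = out$motif_truth,
    cys_positions = out$cys_abs,
    basic_domain = c(spec$basic_domain$start,
                     spec$basic_domain$start + spec$basic_domain$length - 1L),
    seed = spec$seed)
  list(record = rec, truth = truth)
}

#' Generate a reduced-atom dimer fixture with ground truth
#'
#' Builds a homodimer of a synthetic zipper sequence through the coiled-coil
#' builder, with the requested orientation and register shift, and returns
#' the geometrically guaranteed complementary contact pairs as ground truth.
#'
#' @param spec a [zipper_spec()].
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param register_shift 0 (native), 1 (core to 'c') or 3 (core to 'a').
#' @param interhelical_offset axis separation, Angstroem.
#' @return list with `structure` (two-chain [structure3d()]), `record`,
#'   `truth` (`contact_pairs`: data frame of residue pairs expected to form
#'   salt bridges in the native parallel build; plus the zipper truth).
#' @export
generate_dimer_fixture <- function(spec, orientation = c("parallel", "antiparallel"),
                                   register_shift = 0L,
                                   interhelical_offset = 9.8) {
  orientation <- match.arg(orientation)
  gz <- generate_zipper(spec)
  params <- coiled_coil_params(orientation = orientation,
                               interhelical_offset = interhelical_offset)
  monA <- build_zipper_monomer(gz$record$sequence, core_start = 1L,
                               params = params, register_shift = register_shift,
                               chain = "A")
  monB <- build_zipper_monomer(gz$record$sequence, core_start = 1L,
                               params = params, register_shift = register_shift,
                               chain = "B")
  dimer <- build_dimer(monA, monB, params)
  cp <- gz$truth$complementary_pairs
  # in the parallel in-register build, chain A's 'g' tip faces chain B's
  # following-'a' tip and vice versa
  pairs <- if (nrow(cp)) {
    data.frame(resnoA = c(cp$g, cp$a), resnoB = c(cp$a, cp$g))
  } else data.frame(resnoA = integer(), resnoB = integer())
  pairs <- pairs[order(pairs$resnoA), , drop = FALSE]
  rownames(pairs) <- NULL
  list(structure = dimer, record = gz$record,
       truth = c(gz$truth, list(contact_pairs = pairs,
                                orientation = orientation,
                                register_shift = register_shift)))
}

#' Write a simulation fixture set to disk
#'
#' Emits a FASTA (sequence), a PDB (dimer structure, with the seed in a
#' REMARK line) and a sidecar ground-truth JSON next to them. Ground truth
#' is never embedded in the FASTA/PDB payload.
#'
#' @param fixture a [generate_dimer_fixture()] result (or
#'   [generate_zipper()] / [generate_bpc_protein()] result, which writes
#'   FASTA + JSON only).
#' @param dir output directory (created if needed).
#' @param stem file stem; defaults to the record id.
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, stem = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- stem %||% fixture$record$id
  paths <- c(fasta = file.path(dir, paste0(stem, ".fasta")),
             truth = file.path(dir, paste0(stem, ".truth.json")))
  write_fasta_records(list(fixture$record), paths[["fasta"]])
  if (!is.null(fixture$structure)) {
    paths[["pdb"]] <- file.path(dir, paste0(stem, ".pdb"))
    write_structure_pdb(fixture$structure, paths[["pdb"]],
                        remarks = sprintf("SEED %d", fixture$truth$seed))
  }
  jsonlite::write_json(fixture$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
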