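# Known configuration keys (flat key = value with one dot-nesting level).
CONFIG_DEFAULTS <- list(
  fasta = NA_character_, outdir = NA_character_, seed = 1L,
  register = "d", orientation = "parallel",
  min_core = 4L, max_core_mismatch = 1L, comp_weight = 2.0,
  salt_cutoff = 4.0, hbond_cutoff = 3.5, relax_steps = 200L,
  variants = "native,shift1,shift3,coreswap",
  energy.gamma = 0.0072, energy.beta = 0, energy.eps_in = 1,
  energy.eps_out = 80, energy.probe_radius = 1.4, energy.sasa_points = 960L,
  energy.ensemble_n = 1L, energy.ensemble_sigma = 0.3)

CONFIG_INT_KEYS <- c("seed", "min_core", "max_core_mismatch", "relax_steps",
                     "energy.sasa_points", "energy.ensemble_n")
CONFIG_NUM_KEYS <- c("comp_weight", "salt_cutoff", "hbond_cutoff",
                     "energy.gamma", "energy.beta", "energy.eps_in",
                     "energy.eps_out", "energy.probe_radius",
                     "energy.ensemble_sigma")

#' Pipeline run configuration
#'
#' Plain-text configuration for [run_pipeline()]: flat `key = value` pairs
#' with one nesting level expressed as a dot (`energy.gamma = 0.0072`).
#' Unknown keys are errors (fail-fast); the configuration round-trips
#' losslessly through its file form.
#'
#' @param ... overrides of the defaults (see `alacoil:::CONFIG_DEFAULTS`).
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- CONFIG_DEFAULTS
  cfg[names(over)] <- over
  for (k in CONFIG_INT_KEYS) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in CONFIG_NUM_KEYS) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!cfg$register %in% c("d", "a")) stop("register must be 'd' or 'a'")
  if (!cfg$orientation %in% c("parallel", "antiparallel"))
    stop("orientation must be 'parallel' or 'antiparallel'")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path config file path.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  do.call(run_config, setNames(as.list(vals), keys))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  keys <- names(CONFIG_DEFAULTS)          # canonical order
  vals <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, "")
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}

#' @rdname run_config
#' @details `config_hash()` is an md5 over the canonical serialization of the
#'   analytic settings; the `fasta` and `outdir` paths are excluded so the
#'   same analysis run from different locations carries the same hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keys <- setdiff(names(CONFIG_DEFAULTS), c("fasta", "outdir"))
  vals <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, "")
  writeLines(paste(keys, "=", vals), tmp)
  unname(tools::md5sum(tmp))
}

energy_config_from <- function(config) {
  energetics_config(gamma = config$energy.gamma, beta = config$energy.beta,
                    eps_in = config$energy.eps_in, eps_out = config$energy.eps_out,
                    probe_radius = config$energy.probe_radius,
                    sasa_points = config$energy.sasa_points,
                    ensemble_n = config$energy.ensemble_n,
                    ensemble_sigma = config$energy.ensemble_sigma,
                    seed = config$seed)
}

stage_error <- function(stage, msg) stop(sprintf("[%s] %s", stage, msg), call. = FALSE)

VARIANT_SHIFTS <- c(native = 0L, shift1 = 1L, shift3 = 3L)

# Build one dimer variant for a zipper hit on a record; resno numbering
# follows the query (span start .. span end).
build_variant_dimer <- function(record, hit, variant, config) {
  span <- hit$span
  zseq <- substr(record$sequence, span[1], span[2])
  core_start_rel <- hit$core_positions[1] - span[1] + 1L
  params <- coiled_coil_params(orientation = config$orientation)
  shift <- if (variant == "coreswap") 0L else VARIANT_SHIFTS[[variant]]
  mon <- function(ch) {
    m <- build_zipper_monomer(zseq, core_start = core_start_rel,
                              params = params, register_shift = shift, chain = ch)
    a <- m$atoms
    a$resno <- a$resno + span[1] - 1L
    structure3d(a)
  }
  dimer <- build_dimer(mon("A"), mon("B"), params)
  if (variant == "coreswap") {
    core_res <- names(which.max(hit$core_residue_counts))
    swap_to <- if (core_res == "L") "A" else "L"
    pos <- hit$core_positions[seq_chars(record)[hit$core_positions] == core_res]
    dimer <- mutate_core(dimer, core_res, swap_to, pos)
  }
  if (config$relax_steps > 0L)
    dimer <- relax_sidechains(dimer, n_steps = config$relax_steps)
  dimer
}

#' Run the full scan-build-interface-energy pipeline
#'
#' For every FASTA record: writes a motif TSV (zipper + NLS hits), builds
#' the requested dimer variants (native, register-shifted by one and three,
#' core-swapped) from the top zipper hit, writes one PDB + contact TSV +
#' energy JSON per variant, and a per-record summary JSON comparing the
#' variants. A run-level log records package version, seed and config hash.
#' Any stage failure aborts the run with a stage-tagged error; outputs
#' written before the failure are retained.
#'
#' @param config a [run_config()]; `fasta` and `outdir` must be set.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.na(config$fasta) || !file.exists(config$fasta))
    stage_error("input", paste("FASTA not found:", config$fasta))
  if (is.na(config$outdir)) stage_error("input", "outdir not set")
  records <- tryCatch(read_fasta_records(config$fasta),
                      error = function(e) stage_error("scan", conditionMessage(e)))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("alacoil %s", as.character(packageVersion("alacoil"))),
                 sprintf("seed %d", config$seed),
                 sprintf("config_hash %s", hash))
  variants <- strsplit(config$variants, ",")[[1]]
  bad <- setdiff(variants, c(names(VARIANT_SHIFTS), "coreswap"))
  if (length(bad)) stage_error("config", paste("unknown variant(s):",
                                               paste(bad, collapse = ",")))
  ecfg <- energy_config_from(config)
  summary_all <- list()
  for (rec in records) {
    zhits <- tryCatch(detect_ala_zipper(rec, min_core = config$min_core,
                                        max_core_mismatch = config$max_core_mismatch,
                                        register = config$register,
                                        comp_weight = config$comp_weight),
                      error = function(e) stage_error("scan", conditionMessage(e)))
    nhits <- scan_nls(rec)
    write_motif_tsv(rec, zhits, nhits,
                    file.path(config$outdir, paste0(rec$id, "_motifs.tsv")))
    log_lines <- c(log_lines, sprintf("scan %s zipper_hits=%d nls_hits=%d",
                                      rec$id, length(zhits), length(nhits)))
    if (length(zhits) == 0L)
      stage_error("build", paste("no zipper motif detected in", rec$id))
    hit <- zhits[[1L]]
    ventries <- list()
    for (v in variants) {
      dimer <- tryCatch(build_variant_dimer(rec, hit, v, config),
                        error = function(e) stage_error("build", conditionMessage(e)))
      write_structure_pdb(dimer,
                          file.path(config$outdir, paste0(rec$id, "_", v, ".pdb")),
                          remarks = sprintf("SEED %d CONFIG %s", config$seed, hash))
      inv <- tryCatch(interface_inventory(dimer, config$salt_cutoff,
                                          config$hbond_cutoff),
                      error = function(e) stage_error("interface", conditionMessage(e)))
      write_contacts_tsv(inv, file.path(config$outdir,
                                        paste0(rec$id, "_", v, "_contacts.tsv")))
      en <- tryCatch(delta_g_binding(dimer, ecfg),
                     error = function(e) stage_error("energy", conditionMessage(e)))
      write_energy_json(en, file.path(config$outdir,
                                      paste0(rec$id, "_", v, "_energy.json")))
      ventries[[v]] <- list(energy = en, inventory = inv)
      log_lines <- c(log_lines,
                     sprintf("variant %s %s dG=%.4f salt=%d hbond=%d", rec$id, v,
                             en$delta_g_binding, inv$n_salt_bridges, inv$n_hbonds))
    }
    vr <- variant_report(native = ventries$native,
                         shifted_minus1 = ventries$shift1,
                         shifted_plus3 = ventries$shift3,
                         core_swapped = ventries$coreswap)
    summary_all[[rec$id]] <- list(
      record = rec$id,
      zipper = list(span = hit$span, phase = hit$phase,
                    n_core = length(hit$core_positions),
                    n_complementary_pairs = hit$n_complementary_pairs,
                    score = hit$score),
      n_nls_hits = length(nhits),
      variants = vr$table,
      least_stable = vr$least_stable)
  }
  summary <- list(seed = config$seed, config_hash = hash,
                  register = config$register, orientation = config$orientation,
                  records = summary_all)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", na = "null")
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  invisible(config$outdir)
}

#' Compare dimer variants
#'
#' Tabulates binding energy and contact counts of the native,
#' register-shifted (by one and by three) and core-swapped models, with
#' ratios relative to native, and flags the least stable variant (highest
#' binding free energy). Missing variants are reported as absent without
#' aborting; if all present variants tie, nothing is flagged.
#'
#' @param native,shifted_minus1,shifted_plus3,core_swapped lists with
#'   elements `energy` (an [delta_g_binding()] report) and `inventory`
#'   (an [interface_inventory()] result), or `NULL` when absent.
#' @return list with `table` (one row per variant: `variant`, `present`,
#'   `delta_g`, `n_salt_bridges`, `n_hbonds`, `salt_ratio_vs_native`,
#'   `hbond_ratio_vs_native`) and `least_stable` (variant name or `NA`).
#' @export
variant_report <- function(native = NULL, shifted_minus1 = NULL,
                           shifted_plus3 = NULL, core_swapped = NULL) {
  ins <- list(native = native, shifted_minus1 = shifted_minus1,
              shifted_plus3 = shifted_plus3, core_swapped = core_swapped)
  row <- function(name, x) {
    if (is.null(x))
      return(data.frame(variant = name, present = FALSE, delta_g = NA_real_,
                        n_salt_bridges = NA_integer_, n_hbonds = NA_integer_,
                        salt_ratio_vs_native = NA_real_,
                        hbond_ratio_vs_native = NA_real_))
    data.frame(variant = name, present = TRUE,
               delta_g = x$energy$delta_g_binding,
               n_salt_bridges = x$inventory$n_salt_bridges,
               n_hbonds = x$inventory$n_hbonds,
               salt_ratio_vs_native = NA_real_, hbond_ratio_vs_native = NA_real_)
  }
  tab <- do.call(rbind, lapply(names(ins), function(n) row(n, ins[[n]])))
  if (!is.null(native)) {
    for (i in seq_len(nrow(tab))) {
      if (!tab$present[i]) next
      r <- inventory_ratio(ins[[tab$variant[i]]]$inventory, native$inventory)
      tab$salt_ratio_vs_native[i] <- r$salt_ratio
      tab$hbond_ratio_vs_native[i] <- r$hbond_ratio
    }
  }
  present <- which(tab$present)
  least <- NA_character_
  if (length(present) > 1L) {
    dg <- tab$delta_g[present]
    if (max(dg) - min(dg) > 1e-12)
      least <- tab$variant[present[which.max(dg)]]
  }
  list(table = tab, least_stable = least)
}
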