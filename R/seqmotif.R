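#' Protein sequence record
#'
#' Lightweight container for a single protein sequence: an identifier, an
#' uppercase one-letter amino-acid string restricted to the 20 standard
#' residues plus `X`, and a free-form annotation list. All positions reported
#' by the scanners are 1-based and inclusive.
#'
#' @param id character identifier.
#' @param sequence amino-acid string (1-letter, uppercase).
#' @param annotations named list of free-form annotations.
#' @return An object of class `protein_record`.
#' @examples
#' rec <- protein_record("toy", "MKAAAEKAAAEK")
#' @export
protein_record <- function(id, sequence, annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("sequence must be nonempty")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA1, "X"))
  if (length(bad) > 0L)
    stop("sequence contains non-standard residues: ", paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence, annotations = annotations),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Read protein records from a FASTA file
#'
#' Multi-record FASTA with wrapped lines is supported. The first whitespace
#' token of each header becomes the record id; the remainder is kept in the
#' `description` annotation.
#'
#' @param path path to a FASTA file.
#' @return list of [protein_record] objects.
#' @export
read_fasta_records <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("FASTA file contains no records: ", path)
  lapply(seq_along(aas), function(i) {
    header <- names(aas)[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    protein_record(id, toupper(as.character(aas[[i]])),
                   annotations = if (nzchar(desc)) list(description = desc) else list())
  })
}

#' Write protein records to a FASTA file
#'
#' @param records list of [protein_record] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    d <- r$annotations$description
    if (is.null(d)) r$id else paste(r$id, d)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

check_span <- function(record, span) {
  stopifnot(length(span) == 2L)
  if (span[1] < 1L || span[2] > nchar(record$sequence) || span[1] > span[2])
    stop("span [", span[1], ",", span[2], "] out of bounds for sequence of length ",
         nchar(record$sequence))
  invisible(span)
}

#' Assign heptad register labels over a span
#'
#' Labels each residue of `span` with a coiled-coil register letter a--g,
#' cycling with exact period 7. `phase` anchors the register to the whole
#' sequence: position `i` receives letter `(i - 1 + phase) mod 7` of a--g,
#' so assignments over different spans of the same record agree wherever
#' they overlap, and the `phase` reported by [detect_ala_zipper()] can be
#' passed straight in to reproduce the hit's register.
#'
#' @param record a [protein_record].
#' @param span integer vector `c(start, end)`, 1-based inclusive.
#' @param phase integer 0--6.
#' @return object of class `heptad_assignment` with elements `start`, `end`,
#'   `phase` and `labels` (one letter per residue, named by position).
#' @export
assign_heptads <- function(record, span, phase) {
  check_span(record, span)
  stopifnot(phase %in% 0:6)
  pos <- span[1]:span[2]
  labels <- HEPTAD_LETTERS[((pos - 1L + phase) %% 7L) + 1L]
  names(labels) <- pos
  structure(list(start = span[1], end = span[2], phase = as.integer(phase),
                 labels = labels),
            class = "heptad_assignment")
}

#' Per-heptad charge complementarity flags
#'
#' A heptad boundary is flagged complementary when the residue at a 'g'
#' position is acidic (D/E) and the immediately following residue -- the 'a'
#' position of the next heptad -- is basic (K/R). This is the adjacent
#' acidic/basic pairing that flanks the Ala core in group II BPC-type
#' zippers and that faces the partner helix in the dimer.
#'
#' @param assignment a `heptad_assignment` covering the span of interest.
#' @param record the [protein_record] the assignment refers to.
#' @return list with `flags` (logical, named by the 'g' position of each
#'   g/a pair inside the span) and `n_complementary_pairs`.
#' @export
charge_complementarity <- function(assignment, record) {
  stopifnot(inherits(assignment, "heptad_assignment"))
  s <- seq_chars(record)
  pos <- as.integer(names(assignment$labels))
  gpos <- pos[assignment$labels == "g" & pos + 1L <= assignment$end]
  flags <- vapply(gpos, function(p) {
    s[p] %in% c("D", "E") && s[p + 1L] %in% c("K", "R")
  }, logical(1))
  names(flags) <- gpos
  list(flags = flags, n_complementary_pairs = sum(flags))
}

# Complementary g/a pairs counted relative to an Ala-core track: for a core
# residue at position p (register 'd'), the flanking charge pair is (p+3, p+4).
count_complementary_from_core <- function(s, core_track, span_end) {
  n <- 0L
  for (p in core_track) {
    g <- p + 3L; a <- p + 4L
    if (a <= span_end && s[g] %in% c("D", "E") && s[a] %in% c("K", "R"))
      n <- n + 1L
  }
  n
}

#' Detect Alanine-zipper motifs
#'
#' Scans all seven 7-periodic tracks of the sequence for runs of small "core"
#' residues (default Ala, with Gly permitted) spaced exactly 7 apart --
#' the Alacoil signature. A run must contain at least `min_core` core
#' residues and may skip at most `max_core_mismatch` non-core positions.
#' Hits are scored as the number of core matches plus `comp_weight` times the
#' number of complementary acidic('g')/basic('a') flanking pairs, and are
#' returned sorted by decreasing score (ties: leftmost start, then lowest
#' phase). Overlapping hits on the same track are merged into the maximal run.
#'
#' The conserved core is reported at register 'd' by default. Because
#' sequence data alone cannot fix the register of an Alacoil (the same
#' structures are described with cores at 'a'), `register = "a"` flips the
#' reported phase; detection itself is unaffected.
#'
#' @param record a [protein_record].
#' @param min_core minimum number of core residues in a hit.
#' @param max_core_mismatch maximum non-core positions tolerated inside a run.
#' @param permissive_core residue set accepted as core (default `c("A","G")`).
#' @param register report core at `"d"` (default) or `"a"`.
#' @param comp_weight score weight per complementary charge pair.
#' @return list of `ala_zipper_hit` objects, each with `span`,
#'   `core_positions`, `core_residue_counts`, `spacings`, `register`,
#'   `phase`, `n_complementary_pairs` and `score`.
#' @export
detect_ala_zipper <- function(record, min_core = 4L, max_core_mismatch = 1L,
                              permissive_core = c("A", "G"),
                              register = c("d", "a"), comp_weight = 2.0) {
  register <- match.arg(register)
  s <- seq_chars(record)
  L <- length(s)
  if (L == 0L) stop("empty sequence")
  if (L < 7L * min_core)
    stop("sequence shorter than 7 * min_core (", 7L * min_core, ") residues")

  hits <- list()
  for (tr in 0:6) {                      # track: positions == tr+1 (mod 7)
    pos <- seq.int(tr + 1L, L, by = 7L)
    if (length(pos) < min_core) next
    m <- s[pos] %in% permissive_core
    windows <- maximal_core_windows(m, min_core, max_core_mismatch)
    for (w in windows) {
      idx <- w[1]:w[2]
      core_pos <- pos[idx][m[idx]]
      span <- c(core_pos[1], min(core_pos[length(core_pos)] + 6L, L))
      ncomp <- count_complementary_from_core(s, pos[idx], span[2])
      phase_d <- (3L - (core_pos[1] - 1L)) %% 7L
      phase <- if (register == "d") phase_d else (phase_d - 3L) %% 7L
      counts <- table(s[pos[idx]][m[idx]])
      hits[[length(hits) + 1L]] <- structure(list(
        span = as.integer(span),
        core_positions = as.integer(core_pos),
        core_residue_counts = setNames(as.integer(counts), names(counts)),
        spacings = as.integer(diff(core_pos)),
        register = register,
        phase = as.integer(phase),
        n_complementary_pairs = ncomp,
        score = length(core_pos) + comp_weight * ncomp
      ), class = "ala_zipper_hit")
    }
  }
  if (length(hits) == 0L) return(list())
  ord <- order(-vapply(hits, `[[`, 0, "score"),
               vapply(hits, function(h) h$span[1], 0L),
               vapply(hits, `[[`, 0L, "phase"))
  hits[ord]
}

# Maximal windows over a logical match vector: for each left anchor at a
# match, extend right as far as <= k mismatches allows (right end a match),
# then drop windows contained in another. Returns list of c(l, r) indices.
maximal_core_windows <- function(m, min_core, k) {
  n <- length(m)
  out <- list()
  for (l in seq_len(n)) {
    if (!m[l]) next
    mism <- 0L
    r_best <- l
    r <- l
    while (r < n) {
      if (!m[r + 1L]) {
        if (mism + 1L > k) break
        mism <- mism + 1L
      }
      r <- r + 1L
      if (m[r]) r_best <- r
    }
    if (sum(m[l:r_best]) >= min_core) out[[length(out) + 1L]] <- c(l, r_best)
  }
  if (length(out) <= 1L) return(out)
  keep <- rep(TRUE, length(out))
  for (i in seq_along(out)) {
    for (j in seq_along(out)) {
      if (i != j && keep[j] &&
          out[[j]][1] <= out[[i]][1] && out[[i]][2] <= out[[j]][2] &&
          !identical(out[[i]], out[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  unique(out[keep])
}

#' @export
print.ala_zipper_hit <- function(x, ...) {
  cat(sprintf("<ala_zipper_hit> span %d-%d, %d core (%s at '%s'), %d compl. pairs, score %.1f\n",
              x$span[1], x$span[2], length(x$core_positions),
              paste(names(x$core_residue_counts), collapse = "/"),
              x$register, x$n_complementary_pairs, x$score))
  invisible(x)
}

# The three basic NLS-like motifs of group II BPC proteins. x matches any of
# the 20 standard residues (not X, not a gap).
NLS_PATTERNS <- c(
  KxKK    = "K[ACDEFGHIKLMNPQRSTVWY]KK",
  KRxxK   = "KR[ACDEFGHIKLMNPQRSTVWY]{2}K",
  KPKRxKR = "KPKR[ACDEFGHIKLMNPQRSTVWY]KR"
)
NLS_LENGTHS <- c(KxKK = 4L, KRxxK = 5L, KPKRxKR = 7L)

#' Scan for basic NLS-like motifs
#'
#' Reports every match (overlapping matches included) of the three basic
#' nuclear-localization motifs `KxKK`, `KRxxK` and `KPKRxKR`, where `x` is
#' any of the 20 standard residues. Spans are 1-based inclusive.
#'
#' @param record a [protein_record].
#' @return list of `nls_hit` objects with `pattern_id`, `span` and
#'   `matched_text`, sorted by start position.
#' @export
scan_nls <- function(record) {
  s <- record$sequence
  hits <- list()
  for (pid in names(NLS_PATTERNS)) {
    starts <- gregexpr(paste0("(?=", NLS_PATTERNS[[pid]], ")"), s, perl = TRUE)[[1]]
    if (starts[1] == -1L) next
    for (st in as.integer(starts)) {
      en <- st + NLS_LENGTHS[[pid]] - 1L
      hits[[length(hits) + 1L]] <- structure(list(
        pattern_id = pid,
        span = c(st, en),
        matched_text = substr(s, st, en)
      ), class = "nls_hit")
    }
  }
  if (length(hits) == 0L) return(list())
  hits[order(vapply(hits, function(h) h$span[1], 0L),
             vapply(hits, function(h) h$span[2], 0L))]
}

#' @export
print.nls_hit <- function(x, ...) {
  cat(sprintf("<nls_hit> %s at %d-%d (%s)\n", x$pattern_id,
              x$span[1], x$span[2], x$matched_text))
  invisible(x)
}

#' Helical wheel projection
#'
#' Projects a span onto an alpha-helical wheel using the canonical 100
#' degrees per residue, measured clockwise as viewed from the N-terminus.
#' Residues 7 apart are offset by 340 degrees clockwise (a 20 degree
#' counter-clockwise drift per heptad, the origin of supercoiling).
#' `ring_index` increments on each full turn of the wheel.
#'
#' @param record a [protein_record].
#' @param span integer `c(start, end)`.
#' @param phase integer 0--6, used to attach register letters to the entries.
#' @return object of class `wheel_projection` with a data frame `entries`
#'   (`position`, `residue`, `label`, `angle_degrees`, `ring_index`) and
#'   `direction = "clockwise-from-N"`.
#' @export
helical_wheel <- function(record, span, phase = 3L) {
  check_span(record, span)
  s <- seq_chars(record)
  pos <- span[1]:span[2]
  raw <- (pos - span[1]) * 100
  labels <- assign_heptads(record, span, phase)$labels
  structure(list(
    entries = data.frame(
      position = pos,
      residue = s[pos],
      label = unname(labels),
      angle_degrees = raw %% 360,
      ring_index = raw %/% 360,
      stringsAsFactors = FALSE
    ),
    direction = "clockwise-from-N"
  ), class = "wheel_projection")
}

#' Write a motif report TSV
#'
#' One row per hit with columns `record_id`, `motif_type`, `start`, `end`,
#' `phase`, `score` and a JSON `details` column; a single `#`-prefixed header
#' line.
#'
#' @param record the scanned [protein_record].
#' @param zipper_hits list from [detect_ala_zipper()].
#' @param nls_hits list from [scan_nls()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(record, zipper_hits, nls_hits, path) {
  rows <- list()
  for (h in zipper_hits) {
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = record$id, motif_type = "ala_zipper",
      start = h$span[1], end = h$span[2], phase = h$phase, score = h$score,
      details = as.character(jsonlite::toJSON(h[c("core_positions", "spacings",
                                                  "register", "n_complementary_pairs")],
                                              auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  }
  for (h in nls_hits) {
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = record$id, motif_type = paste0("nls_", h$pattern_id),
      start = h$span[1], end = h$span[2], phase = NA_integer_, score = NA_real_,
      details = as.character(jsonlite::toJSON(list(matched_text = h$matched_text),
                                              auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), motif_type = character(),
               start = integer(), end = integer(), phase = integer(),
               score = numeric(), details = character())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}
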