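test_that("heptad labels cycle with exact period 7 and honour the phase", {
  rec <- random_record(120, seed = 1)
  for (phase in 0:6) {
    ha <- assign_heptads(rec, c(10, 100), phase)
    lab <- ha$labels
    expect_true(all(lab[seq_along(lab)[-(1:7)]] == lab[seq_along(lab)[-(1:7)] - 7]))
    # any 7-residue window contains each of a-g exactly once
    for (w in c(1, 30, 80)) expect_setequal(lab[w:(w + 6)], letters[1:7])
  }
  # all 7 phases give distinct label vectors, each a cyclic shift of phase 0
  vecs <- lapply(0:6, function(p) unname(assign_heptads(rec, c(1, 21), p)$labels))
  expect_length(unique(vapply(vecs, paste, "", collapse = "")), 7L)
  base <- vecs[[1]]
  for (p in 1:6) {
    shifted <- letters[1:7][((match(base, letters[1:7]) - 1 + p) %% 7) + 1]
    expect_identical(vecs[[p + 1]], shifted)
  }
})

test_that("phase anchoring a 'd' at position 41 labels 48..76 as 'd' too", {
  bp <- generate_bpc_protein(bpc_spec(seed = 11))
  phase <- (3 - (41 - 1)) %% 7    # core at 41 -> 'd'
  ha <- assign_heptads(bp$record, c(41, 82), phase)
  expect_identical(unname(ha$labels[as.character(c(41, 48, 55, 62, 69, 76))]),
                   rep("d", 6))
})

test_that("heptad assignment rejects out-of-bounds spans", {
  rec <- random_record(50, seed = 2)
  expect_error(assign_heptads(rec, c(0, 10), 0), "bounds")
  expect_error(assign_heptads(rec, c(40, 51), 0), "bounds")
})

test_that("the planted group-II zipper is recovered exactly", {
  gz <- generate_zipper(zipper_spec(n_heptads = 6, seed = 17))
  hits <- detect_ala_zipper(gz$record)
  expect_gte(length(hits), 1L)
  top <- hits[[1]]
  expect_identical(top$core_positions, gz$truth$core_positions)
  expect_identical(top$spacings, rep(7L, 5))
  expect_identical(top$span, gz$truth$span)
  expect_identical(top$phase, gz$truth$phase)
  expect_identical(top$register, "d")
})

test_that("sequences without small core residues yield no zipper hits", {
  rec <- protein_record("none", paste(rep("KDSTLVE", 8), collapse = ""))
  expect_identical(detect_ala_zipper(rec), list())
})

test_that("zipper detection equals the exhaustive window/phase oracle", {
  recs <- c(lapply(1:6, function(s) random_record(120, seed = s)),
            lapply(7:9, function(s) random_record(200, seed = s)),
            list(generate_zipper(zipper_spec(seed = 41))$record,
                 generate_zipper(zipper_spec(n_heptads = 8, seed = 42,
                                             complementarity_fraction = 0.5))$record))
  for (rec in recs) {
    got <- detect_ala_zipper(rec)
    exp <- brute_force_zipper(rec)
    expect_length(got, length(exp))
    for (k in seq_along(got)) {
      expect_identical(got[[k]]$span, as.integer(exp[[k]]$span))
      expect_identical(got[[k]]$core_positions, as.integer(exp[[k]]$core_positions))
      expect_identical(got[[k]]$phase, as.integer(exp[[k]]$phase))
      expect_equal(got[[k]]$n_complementary_pairs, exp[[k]]$n_complementary_pairs)
      expect_equal(got[[k]]$score, exp[[k]]$score)
    }
  }
})

test_that("planted zipper span and phase are recovered across seeds", {
  for (s in 1:20) {
    gz <- generate_zipper(zipper_spec(n_heptads = 6, seed = s,
                                      complementarity_fraction = 0.8))
    top <- detect_ala_zipper(gz$record)[[1]]
    expect_identical(top$core_positions, gz$truth$core_positions)
    expect_identical(top$phase, gz$truth$phase)
  }
})

test_that("register option 'a' flips the reported phase only", {
  gz <- generate_zipper(zipper_spec(seed = 23))
  hd <- detect_ala_zipper(gz$record, register = "d")[[1]]
  ha <- detect_ala_zipper(gz$record, register = "a")[[1]]
  expect_identical(hd$core_positions, ha$core_positions)
  expect_identical(ha$phase, (hd$phase - 3L) %% 7L)
  lab <- assign_heptads(gz$record, hd$span, ha$phase)$labels
  expect_identical(unname(lab[as.character(hd$core_positions[1])]), "a")
})

test_that("NLS scanning matches the printed motif coordinates", {
  # KAKK placed with its first K at position 192
  s <- c(rep("G", 191), "K", "A", "K", "K", rep("G", 5))
  rec <- protein_record("nls1", paste(s, collapse = ""))
  hits <- scan_nls(rec)
  expect_length(hits, 1L)
  expect_identical(hits[[1]]$pattern_id, "KxKK")
  expect_identical(hits[[1]]$span, c(192L, 195L))

  s2 <- c(rep("G", 164), "K", "P", "K", "R", "S", "K", "R", rep("G", 10))
  hits2 <- scan_nls(protein_record("nls2", paste(s2, collapse = "")))
  expect_identical(hits2[[1]]$pattern_id, "KPKRxKR")
  expect_identical(hits2[[1]]$span, c(165L, 171L))
  expect_identical(hits2[[1]]$matched_text, "KPKRSKR")

  expect_identical(scan_nls(protein_record("pg", strrep("G", 40))), list())
})

test_that("NLS scanning equals the naive sliding-window oracle", {
  for (s in 1:50) {
    rec <- random_record(150, seed = 100 + s,
                         alphabet = c("K", "R", "P", "G", "A", "S"))
    got <- scan_nls(rec)
    exp <- naive_scan_nls(rec)
    expect_length(got, length(exp))
    for (k in seq_along(got)) {
      expect_identical(got[[k]]$pattern_id, exp[[k]]$pattern_id)
      expect_identical(got[[k]]$span, as.integer(exp[[k]]$span))
      expect_identical(got[[k]]$matched_text, exp[[k]]$matched_text)
    }
  }
})

test_that("helical wheel angles follow the 100-degree clockwise rule", {
  rec <- random_record(80, seed = 5)
  w <- helical_wheel(rec, c(10, 60), phase = 3)
  e <- w$entries
  expect_identical(e$angle_degrees[1], 0)
  expect_identical(e$angle_degrees[e$position == 10 + 18], (18 * 100) %% 360)
  # residues 7 apart: 340 degrees clockwise offset
  for (i in seq_len(nrow(e) - 7)) {
    expect_equal((e$angle_degrees[i + 7] - e$angle_degrees[i]) %% 360, 340)
  }
  expect_identical(e$ring_index[1:4], c(0, 0, 0, 0) + (0:3 * 100) %/% 360)
  expect_identical(w$direction, "clockwise-from-N")
})

test_that("charge complementarity flags the adjacent acidic-g/basic-a pair", {
  # ...E at 'g' immediately followed by K at 'a' of the next heptad
  rec <- protein_record("cc", "ASTEKSSASTDRSSASTDDSS")
  ha <- assign_heptads(rec, c(1, 21), 3)  # position 1 = 'd', so 'g' at 4, 11, 18
  cc <- charge_complementarity(ha, rec)
  expect_identical(unname(cc$flags), c(TRUE, TRUE, FALSE))
  expect_identical(cc$n_complementary_pairs, 2L)

  ala <- protein_record("ala", strrep("A", 21))
  cc0 <- charge_complementarity(assign_heptads(ala, c(1, 21), 3), ala)
  expect_identical(cc0$n_complementary_pairs, 0L)
})

test_that("generator bookkeeping matches the detected complementary count", {
  gz <- generate_zipper(zipper_spec(n_heptads = 8, seed = 99,
                                    complementarity_fraction = 0.5))
  top <- detect_ala_zipper(gz$record)[[1]]
  expect_identical(top$n_complementary_pairs, gz$truth$n_complementary_pairs)
  # and fraction 0 gives zero complementary pairs
  gz0 <- generate_zipper(zipper_spec(n_heptads = 8, seed = 99,
                                     complementarity_fraction = 0))
  expect_identical(detect_ala_zipper(gz0$record)[[1]]$n_complementary_pairs, 0L)
})

test_that("FASTA i/o round-trips records and the motif TSV is well formed", {
  recs <- list(generate_zipper(zipper_spec(seed = 1))$record,
               generate_bpc_protein(bpc_spec(seed = 2))$record)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_records(recs, fa)
  back <- read_fasta_records(fa)
  expect_identical(vapply(back, `[[`, "", "sequence"),
                   vapply(recs, `[[`, "", "sequence"))
  expect_identical(vapply(back, `[[`, "", "id"),
                   vapply(recs, `[[`, "", "id"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  rec <- recs[[2]]
  write_motif_tsv(rec, detect_ala_zipper(rec), scan_nls(rec), tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "^#record_id\t")
  body <- read.delim(tsv, header = FALSE, skip = 1)
  expect_identical(ncol(body), 7L)
  expect_true(any(grepl("ala_zipper", body[[2]])))
  expect_true(sum(grepl("^nls_", body[[2]])) == 3L)
})
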