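test_that("ideal helix geometry matches the parametric expectations", {
  h <- build_ideal_helix("ADEKLRSTV", helix_params())
  a <- h$atoms
  ca <- as.matrix(a[a$elety == "CA", c("x", "y", "z")])
  dd <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dd - 3.8) <= 0.1))
  # axial rise
  expect_equal(ca[nrow(ca), 3] - ca[1, 3], (nrow(ca) - 1) * 1.5)
  # 18-residue helix: end-to-end CA rise ~ 17 * 1.5
  h18 <- build_ideal_helix(strrep("A", 18))
  ca18 <- as.matrix(h18$atoms[h18$atoms$elety == "CA", c("x", "y", "z")])
  expect_equal(ca18[18, 3] - ca18[1, 3], 25.5)
  # tip lengths follow the residue table
  tips <- a[a$elety == "TIP", ]
  cas <- a[a$elety == "CA", ]
  lens <- sqrt(rowSums((tips[, c("x", "y", "z")] -
                          cas[match(tips$resno, cas$resno), c("x", "y", "z")])^2))
  expect_equal(unname(lens), unname(c(ALA = 1.5, ASP = 3.7, GLU = 5.0, LYS = 6.4,
                              LEU = 3.9, ARG = 7.3, SER = 2.4, THR = 2.4,
                              VAL = 2.4)[tips$resid]))
})

test_that("single-residue and degenerate inputs are handled", {
  h1 <- build_ideal_helix("K")
  expect_identical(nrow(h1$atoms), 6L)            # N CA C O CB TIP
  hg <- build_ideal_helix("G")
  expect_identical(sort(hg$atoms$elety), sort(c("N", "CA", "C", "O")))
  expect_error(build_ideal_helix("AZB"), "unknown")
  expect_error(build_ideal_helix(""), "nonempty")
})

test_that("threading preserves the template backbone bit-for-bit", {
  query <- generate_zipper(zipper_spec(seed = 3))$record
  tmpl <- build_ideal_helix(strrep("L", 42), coiled_coil_params())
  thr <- thread_sequence(query, tmpl, threading_map(c(1, 42), c(1, 42), 0))
  bbt <- tmpl$atoms[tmpl$atoms$elety %in% c("N", "CA", "C", "O"), ]
  bbq <- thr$atoms[thr$atoms$elety %in% c("N", "CA", "C", "O"), ]
  expect_identical(bbq[, c("x", "y", "z")], bbt[, c("x", "y", "z")])
  expect_identical(unique(thr$atoms$resid[thr$atoms$resno %in%
                     detect_ala_zipper(query)[[1]]$core_positions &
                     thr$atoms$elety == "CA"]), "ALA")
  # threading a sequence onto its own built backbone: backbone RMSD 0
  own <- build_ideal_helix(query$sequence, coiled_coil_params())
  thr0 <- thread_sequence(query, own, threading_map(c(1, 42), c(1, 42), 0))
  expect_equal(superpose_and_rmsd(own, thr0)$rmsd, 0, tolerance = 1e-12)
})

test_that("native and shifted threading maps have the printed span sizes", {
  # native: query 37..81 onto template 278..322 = 45 residue pairs
  m0 <- threading_map(c(37, 81), c(278, 322), 0)
  expect_identical(diff(m0$query_span) + 1L, 45L)
  # shift-by-one variant: template window 268..308 = 41 pairs, core at 'c'
  m1 <- threading_map(c(37, 77), c(268, 308), -1L)
  expect_identical(diff(m1$template_span) + 1L, 41L)
  tmpl <- build_ideal_helix(strrep("L", 41), coiled_coil_params(),
                            start_resno = 268L)
  query <- generate_bpc_protein(bpc_spec(seed = 9))$record
  thr <- thread_sequence(query, tmpl, m1)
  expect_identical(nrow(unique(thr$atoms[, c("chain", "resno")])), 41L)
  expect_identical(attr(thr, "threading")$core_letter, "c")
  expect_error(thread_sequence(query, tmpl, threading_map(c(37, 78), c(268, 308))),
               "equal length")
})

test_that("register-shift semantics land the core on 'c' and 'a'", {
  expect_identical(register_letter(0L), "d")
  expect_identical(register_letter(-1L), "c")
  expect_identical(register_letter(-3L), "a")
  # asserted on labels: shifting the anchor by k moves the core letter back
  gz <- generate_zipper(zipper_spec(seed = 7))
  p0 <- gz$truth$phase
  core <- as.character(gz$truth$core_positions)
  lab1 <- assign_heptads(gz$record, gz$truth$span, (p0 - 1L) %% 7L)$labels
  lab3 <- assign_heptads(gz$record, gz$truth$span, (p0 - 3L) %% 7L)$labels
  expect_true(all(lab1[core] == "c"))
  expect_true(all(lab3[core] == "a"))
})

test_that("core swap mutates names and tips but never the backbone", {
  fx <- generate_dimer_fixture(zipper_spec(seed = 13))
  core <- fx$truth$core_positions
  mut <- mutate_core(fx$structure, "A", "L", core)
  expect_identical(unique(mut$atoms$resid[mut$atoms$resno %in% core &
                                            mut$atoms$elety == "CA"]), "LEU")
  expect_equal(superpose_and_rmsd(fx$structure, mut)$rmsd, 0, tolerance = 1e-12)
  # double application returns the original structure
  back <- mutate_core(mut, "L", "A", core)
  expect_equal(back$atoms[order(back$atoms$chain, back$atoms$resno, back$atoms$elety),
                          c("resid", "elety", "x", "y", "z")],
               fx$structure$atoms[order(fx$structure$atoms$chain,
                                        fx$structure$atoms$resno,
                                        fx$structure$atoms$elety),
                                  c("resid", "elety", "x", "y", "z")],
               ignore_attr = TRUE)
  expect_identical(mutate_core(fx$structure, "A", "L", integer()), fx$structure)
  expect_error(mutate_core(fx$structure, "E", "Q", core), "do not carry")
})

test_that("superposition recovers rigid motions and known deviations", {
  fx <- generate_dimer_fixture(zipper_spec(seed = 19))
  s0 <- superpose_and_rmsd(fx$structure, fx$structure)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  R <- rotation_matrix(c(1, 2, 3), 67)
  moved <- transform_structure(fx$structure, R, c(5, -3, 11))
  expect_lt(superpose_and_rmsd(fx$structure, moved)$rmsd, 1e-6)
  expect_lt(superpose_and_rmsd(moved, fx$structure)$rmsd, 1e-6)
  # invariance under simultaneous rigid motion of both structures
  mutA <- mutate_core(fx$structure, "A", "L", fx$truth$core_positions)
  r1 <- superpose_and_rmsd(fx$structure, relax_sidechains(mutA, 5))$rmsd
  bothA <- transform_structure(fx$structure, R, c(1, 2, 3))
  bothB <- transform_structure(relax_sidechains(mutA, 5), R, c(1, 2, 3))
  expect_equal(superpose_and_rmsd(bothA, bothB)$rmsd, r1, tolerance = 1e-9)
  expect_error(superpose_and_rmsd(fx$structure, build_ideal_helix("AAAA")),
               "different atom counts")
})

test_that("three-point toy superposition matches the closed form", {
  h <- 0.9
  A <- toy_structure(atom("A", 1, "GLY", "CA", c(-1, 0, 0)),
                     atom("A", 2, "GLY", "CA", c(0, 0, 0)),
                     atom("A", 3, "GLY", "CA", c(1, 0, 0)))
  B <- toy_structure(atom("A", 1, "GLY", "CA", c(-1, 0, 0)),
                     atom("A", 2, "GLY", "CA", c(0, h, 0)),
                     atom("A", 3, "GLY", "CA", c(1, 0, 0)))
  got <- superpose_and_rmsd(A, B, atom_selection = "CA")$rmsd
  expect_equal(got, h * sqrt(2) / 3, tolerance = 1e-10)
})

test_that("superposition agrees with the bio3d reference implementation", {
  fx <- generate_dimer_fixture(zipper_spec(seed = 21))
  per <- transform_structure(relax_sidechains(fx$structure, 10),
                             rotation_matrix(c(0, 1, 1), 33), c(2, 2, -4))
  sel <- which(fx$structure$atoms$elety %in% c("N", "CA", "C", "O"))
  fixed <- as.numeric(t(as.matrix(fx$structure$atoms[sel, c("x", "y", "z")])))
  mobile <- as.numeric(t(as.matrix(per$atoms[sel, c("x", "y", "z")])))
  ref <- bio3d::rmsd(fixed, mobile, fit = TRUE)
  got <- superpose_and_rmsd(fx$structure, per)$rmsd
  expect_equal(got, ref, tolerance = 1e-4)
})

test_that("dimer assembly places chains and contacts by construction", {
  gz <- generate_zipper(zipper_spec(seed = 31))
  par <- coiled_coil_params()
  monA <- build_zipper_monomer(gz$record$sequence, 1, par, chain = "A")
  monB <- build_zipper_monomer(gz$record$sequence, 1, par, chain = "B")
  dim_par <- build_dimer(monA, monB, par)
  expect_identical(chain_ids(dim_par), c("A", "B"))
  inv <- interface_inventory(dim_par)
  expect_gte(inv$n_salt_bridges, 6 - 1)
  # antiparallel: chain B first-residue CA nearest chain A last-residue CA
  anti <- coiled_coil_params(orientation = "antiparallel")
  dim_anti <- build_dimer(monA, monB, anti)
  a <- dim_anti$atoms
  caA <- as.matrix(a[a$chain == "A" & a$elety == "CA", c("x", "y", "z")])
  caB1 <- as.numeric(a[a$chain == "B" & a$elety == "CA" & a$resno == 1,
                       c("x", "y", "z")])
  # N->C direction reversed: B's first CA sits at the far (C-terminal) end
  # of chain A, not the near end, and B's z decreases with resno
  dists <- sqrt(colSums((t(caA) - caB1)^2))
  expect_lt(dists[length(dists)], dists[1])
  expect_gte(unname(which.min(dists)), length(dists) - 2L)
  zB <- a$z[a$chain == "B" & a$elety == "CA"]
  expect_true(all(diff(zB) < 0))
  # 100 A separation: no intermolecular contacts at all
  far <- build_dimer(monA, monB, coiled_coil_params(interhelical_offset = 100))
  inv_far <- interface_inventory(far)
  expect_identical(inv_far$n_salt_bridges + inv_far$n_hbonds, 0L)
})

test_that("side-chain relaxation is monotone, bounded and clash-reducing", {
  fx <- generate_dimer_fixture(zipper_spec(seed = 37))
  expect_identical(relax_sidechains(fx$structure, 0), fx$structure)
  rx <- relax_sidechains(fx$structure, 200)
  tr <- attr(rx, "relax_trace")
  expect_length(tr, 201L)
  expect_true(all(diff(tr) <= 1e-12))
  expect_lt(tr[length(tr)], tr[1])
  # backbone frozen
  bb0 <- fx$structure$atoms[fx$structure$atoms$elety != "TIP", c("x", "y", "z")]
  bb1 <- rx$atoms[rx$atoms$elety != "TIP", c("x", "y", "z")]
  expect_identical(bb0, bb1)
  # two overlapping tips move apart
  t0 <- toy_structure(
    atom("A", 1, "GLU", "CA", c(0, 0, 0)),
    atom("A", 1, "GLU", "TIP", c(2.5, 0, 0), radius = 2),
    atom("B", 1, "LYS", "CA", c(5, 2, 0)),
    atom("B", 1, "LYS", "TIP", c(3.0, 0.8, 0), radius = 2))
  t1 <- relax_sidechains(t0, 100, step_size = 0.05)
  d0 <- abs(t0$atoms$x[2] - t0$atoms$x[4])
  d1 <- abs(t1$atoms$x[2] - t1$atoms$x[4])
  expect_gt(d1, d0)
})

test_that("PDB i/o round-trips the reduced representation", {
  fx <- generate_dimer_fixture(zipper_spec(seed = 43))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(fx$structure, pdb, remarks = "SEED 43")
  expect_match(readLines(pdb)[1], "^REMARK.*SEED 43")
  back <- read_structure_pdb(pdb)
  expect_identical(nrow(back$atoms), nrow(fx$structure$atoms))
  expect_identical(back$atoms$resid, fx$structure$atoms$resid)
  expect_identical(back$atoms$chain, fx$structure$atoms$chain)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(fx$structure$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # charges/radii reassigned by the reduced rules
  expect_identical(sum(back$atoms$charge != 0), sum(fx$structure$atoms$charge != 0))
})
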