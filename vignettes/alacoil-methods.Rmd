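---
title: "Alanine-zipper coiled-coils: detection, reduced-atom models and interface energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alanine-zipper coiled-coils: detection, reduced-atom models and interface energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alacoil)
```

## The scientific problem

Classical leucine zippers dimerize through a hydrophobic core: large aliphatic
side chains at the heptad 'a'/'d' positions pack knobs-into-holes between the
two helices. Alanine zippers (Alacoils) are a variant in which the core
positions carry alanine (or even glycine), a side chain far too small to form
such a core. In the group II BBR/BPC family of plant GAGA-binding
transcription factors, the N-terminal dimerization domain is exactly this
kind of zipper: invariant alanines spaced 7 residues apart, flanked by a
conserved charge pattern — an acidic residue at the 'g' position immediately
followed by a basic residue at the 'a' position of the next heptad. The
working model is that the dimer is held together not by core packing but by
interhelical salt bridges and charge-stabilized hydrogen bonds between those
flanking residues, with the tiny core residues merely keeping the helices
close enough for the charges to meet. The same proteins carry a basic region
containing three short NLS-like motifs (`KPKRxKR`, `KRxxK`, `KxKK`) and a
C-terminal basic DNA-binding domain with five invariant cysteines.

`alacoil` implements the desk-scale version of this analysis: sequence-level
motif detection, reduced-atom dimer model building with register-shifted and
core-swapped variants, an interface contact inventory, and an MM-PBSA-style
binding free-energy decomposition — together with a seeded synthetic-data
generator so that every stage runs and is testable without any external
sequence or structure.

## Sequence analysis

**Heptad register.** `assign_heptads()` labels residues a–g with exact
period 7. The phase anchors the register to sequence position 1, so
assignments over different spans of one record agree wherever they overlap.
The conserved core is reported at register 'd' by default. Sequence data
alone cannot decide between the 'd' and 'a' presentations of an Alacoil, and
the dimer models are compatible with both; `detect_ala_zipper(register =
"a")` therefore flips the reported phase without changing detection. We
expose the ambiguity rather than resolving it.

**Zipper detection.** All seven 7-periodic tracks are scanned for maximal
runs of core residues. Defaults: at least `min_core = 4` core positions, at
most `max_core_mismatch = 1` non-core position inside a run, and a
permissive core set of `{A, G}` — glycine is included because bacterial
relatives of these domains carry Gly in place of Ala, indicating that any
sufficiently small residue is tolerated. Hits are scored as
`n_core + 2 * n_complementary_pairs`. The weight 2 is a package choice, set
so that a fully charge-complementary 4-heptad zipper (score 4 + 2·3 = 10)
outranks a bare 6-heptad Ala track (score 6): the charge pattern, not sheer
core length, is the discriminating signature of this family. Ties break to
the leftmost start, then the lowest phase, for determinism.

**Charge complementarity.** A heptad boundary is flagged complementary when
the residue at 'g' is D/E and the *immediately following* residue — the 'a'
of the next heptad — is K/R. We read the conserved pattern as this adjacent
g→a pair: it is the pair that ends up geometrically opposed across the dimer
interface, and it makes the generator's bookkeeping, the sequence-level flag
and the structural contact coincide (a generator set to complementarity 0
produces exactly 0 flags).

**NLS motifs.** `scan_nls()` reports every match, overlapping matches
included, of the three basic motifs, with `x` matching any of the 20
standard residues (never `X`, never a gap). Spans are 1-based inclusive.
The canonical coordinates on the group II architecture are 165–171, 184–188
and 192–195; the motif-to-motif span 165→195 is 31 residues, which is the
length arithmetic the package treats as authoritative for the basic region.

## Reduced-atom structure model

Full side chains are replaced by one pseudo-atom per residue: each residue
carries backbone N, CA, C, O on an ideal helix, a CB, and a `TIP` pseudo-atom
along the CA→CB direction whose distance from CA scales with side-chain
reach (Å): Asp 3.7, Glu 5.0, Lys 6.4, Arg 7.3, His 4.6, Leu 3.9, Ala 1.5
(its CB), others 2.4; glycine carries no side-chain atoms. Formal charges of
±1e sit on the tips of D/E (−) and K/R (+); His is neutral by default
(`his_charged` switches it). This representation keeps exactly the degrees
of freedom the interface logic needs — which charged groups can reach which —
at a scale where hundreds of models can be built and scored per minute.

**Helix parameters.** Defaults are the canonical values: rise 1.5 Å/residue,
twist 100°/residue, CA radius 2.3 Å, interhelical separation 9.8 Å.
For dimers, `coiled_coil_params()` uses twist 720/7 ≈ 102.86°/residue — the
straightened average of a supercoiled coiled-coil (3.5 residues/turn). With
this twist the heptad stripes stay azimuthally aligned along the whole
chain, so the interface of an arbitrarily long dimer can be represented with
two straight parallel axes instead of an explicit Crick supercoil; the
superhelix radius/pitch fields are carried as metadata. The cost of the
straightening is that the 20°-per-heptad azimuthal drift that motivates
supercoiling is absorbed into the twist rather than modelled.

**Dimer assembly.** Monomers are built with the core stripe facing +x;
chain B is rotated 180° about the axis direction and translated, so the
acidic 'g' tips of one chain land next to the basic 'a' tips of the other.
By construction, a fully complementary parallel dimer forms at least
`n_heptads − 1` salt bridges. In antiparallel mode chain B is instead
rotated 180° about the axis perpendicular to both the helix axis and the
interhelical vector, which reverses its N→C direction and turns its charged
stripe away from the interface — the geometric statement that this charge
architecture cannot pair antiparallel.

**Register shifts.** Re-threading the sequence k positions along the
template moves the core letter from 'd' to `(d − k) mod 7`: shift 1 lands it
on 'c', shift 3 on 'a' (`register_letter()`), matching the two shifted
variants of the native model. Geometrically a shift rotates the charged
stripe by k·102.86° off the interface seam. In this single-seam reduced
geometry *any* shift therefore breaks the charge pairing; the builder's
rotation direction is chosen so that the shift-3 model remains more
favorable than the shift-1 model, reproducing the qualitative ordering
(shift-1 least stable) but not the full-atom finding that the shift-3
register is essentially as good as native. That finding depends on the
two-stripe ('a' and 'd') interface of a genuinely supercoiled dimer, which
is outside this representation — a known limitation.

**Relaxation.** `relax_sidechains()` performs greedy gradient descent on a
soft-sphere overlap energy of the tip atoms (backbone frozen, tips
re-projected onto their fixed CA–tip distance each step; steps that do not
lower the energy are rejected with step halving, so the energy trace is
non-increasing and the procedure is deterministic). The pipeline default of
200 steps removes the worst clashes of the as-built models; dimer-scale
relaxation can be run longer. This replaces force-field minimization: it is
a clash-removal device, not an energy model.

## Interface contacts

Salt bridge: minimum distance between charged groups (tips in reduced mode;
terminal N/O atoms in full-atom mode) of an acidic and a basic residue on
opposite chains ≤ 4.0 Å — the common literature criterion; the cutoff is a
config key. Hydrogen bond: donor/acceptor heavy atoms (backbone N/O,
side-chain N/O of polar residues, polar tips) on opposite chains within
3.5 Å, requiring at least one oxygen in the pair; because reduced models
carry no hydrogens, the D–H⋯A angle test (≥120°) activates only when
explicit hydrogens are present in the input. Each residue pair is reported
once, at its minimum distance, typed by its strongest interaction (salt
bridge first). Contact detection is validated against an independent
all-pairs brute-force oracle in the test suite.

## Binding-energy decomposition

Each entity (complex, monomer A, monomer B — monomers extracted from the
complex with identical coordinates, the single-trajectory convention) is
scored as

  G = E_gas + G_polar + G_sa

* `E_gas`: pairwise Coulomb `k q_i q_j / (ε_in r_ij)` with
  k = 332.0636 kcal·Å·mol⁻¹·e⁻², ε_in = 1; a Lennard-Jones 12-6 term is
  available for full-atom input and off in reduced mode, where steric
  validity is the builder's job. Internal bonded terms are not computed:
  with identical monomer and complex coordinates they cancel identically in
  the binding difference (asserted in the tests).
* `G_polar`: generalized-Born solvation with the Still pairwise function
  `f_GB = sqrt(r² + R_i R_j exp(−r²/(4 R_i R_j)))`, self-terms included, and
  the dielectric pair ε_in = 1, ε_out = 80. A single ion recovers the Born
  equation exactly. GB is an analytic stand-in for a finite-difference
  Poisson–Boltzmann solver, which is out of desk scope; the package states
  this as a representation choice, not an approximation it attempts to
  correct. Default Born radii: tips 2.0 Å, backbone N 1.55, O 1.50,
  C 1.70 Å (configurable).
* `G_sa = γ·SASA + β` exactly, with the standard γ = 0.0072 kcal·mol⁻¹·Å⁻²
  and β = 0. SASA is Shrake–Rupley sphere sampling on a deterministic
  golden-spiral point set (960 points/atom, probe 1.4 Å), implemented in
  C++; an isolated sphere is reproduced to well under 1%, and a
  deterministic tie rule assigns surface points shared by exactly coincident
  atoms to the lower-index atom so duplicates are not double-counted.

`ΔG_binding = G(complex) − G(A) − G(B)`. The conformational entropy term is
*not* computed — normal-mode analysis on a pseudo-atom model would be
meaningless — and every report carries an explicit "entropy omitted" field.
Snapshot averaging over a trajectory is replaced by an optional seeded
Gaussian conformer ensemble (`ensemble_n` jittered copies, σ = 0.3 Å); the
conventional ensemble size mirroring 500 averaged snapshots is 500, but the
default configuration evaluates the single structure deterministically
(`ensemble_n = 1`), because the reduced model has no trajectory to emulate
and the single-structure result is exactly reproducible.

Because Coulomb and GB are rotation-exact but sampled SASA is not, ΔG is
invariant under rigid motion only to within the SASA sampling resolution
(≲0.1 kcal/mol at 960 points).

The absolute ΔG values of reduced models with formal charges are not
comparable to full-atom MM-PBSA numbers and the package makes no claim that
they are; all energetic conclusions are *orderings* on matched geometries:
parallel complementary < antiparallel; complementary < charge-scrambled;
core removal does not flip the sign of a charge-driven dimer.

## The synthetic generator

`generate_zipper()` lays a zipper segment out core-first: core residue at
positions 1, 8, 15, …, the charge pair at core+3 ('g') and core+4 (next
'a'). Each pair is complementary (acidic g, basic a) with probability
`complementarity_fraction`; otherwise both positions receive the *same*
random sign, which breaks the interhelical attraction — the charge-scrambled
control. Defaults encode the study conditions: 6 heptads (anchors at
positions 41…76 when embedded at the canonical offset 41), Ala core at 'd',
full complementarity, seed-deterministic output.

`generate_bpc_protein()` assembles the full group II architecture: zipper at
offset 41, the three NLS motifs planted at 165/184/192, and a C-terminal
basic domain with exactly five cysteines. Two composition choices keep the
fixtures honest: filler residues are drawn uniformly from residues that are
neither possible core residues, nor charged, nor Pro/Cys, so fillers cannot
create spurious zipper, charge or NLS signals; and the basic domain draws
its basicity from Arg/His rather than Lys, so the K-anchored NLS patterns
cannot match outside the planted motifs. A "hard mode"
(`filler_composition = "natural"`) switches to background amino-acid
frequencies and deliberately gives up these guarantees. Ground truth is
written as a sidecar JSON, never embedded in FASTA/PDB payloads, so
detectors cannot read the answer from their input.

What the generator does **not** emulate: real sequence divergence and
phylogenetic correlation, variable heptad spacing, partially helical or
disordered zippers, and real side-chain rotamers. Passing the recovery and
ordering suites therefore demonstrates internal consistency of detector,
builder and scorer under the stated signal model — not detection performance
on natural proteomes.

## Pipeline and reproducibility

`run_pipeline()` chains scan → build (native, shift-1, shift-3, core-swap) →
interface → energy → summary for every FASTA record, under a flat
`key = value` config with one dot-nesting level. Unknown keys are errors:
silent config typos are the main reproducibility hazard in pipelines of
this kind. Every output carries the seed and an md5 config hash (computed
over the analytic settings, excluding input/output paths); the run log
records versions, seed and hash and no timestamps, so identical config+seed
reproduce byte-identical output trees — a property the test suite asserts
literally.

## Problem sizes and numerical choices

The test and acceptance suites run 6-heptad (42-residue) zippers — ~500
atoms per dimer — with 200-seed recovery and ordering sweeps, 960 SASA
points, and 200-step relaxations; a full sweep completes in a few minutes on
one CPU. Degenerate inputs are defined rather than left to chance: empty
sequences and zero-length spans are errors; glycine builds without
side-chain atoms; coincident duplicate atoms share their surface by the
tie rule above; zero interatomic distance between charges is an error;
superposition excludes reflections (proper rotations only); equal-score
zipper hits break ties leftmost-then-lowest-phase.
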