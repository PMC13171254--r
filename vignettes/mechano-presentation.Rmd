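---
title: "Quantifying mechano-presentation: steric shielding analysis of force-unfolded protein modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mechano-presentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Von Willebrand factor (VWF) is the canonical mechanosensitive plasma
protein: under resting flow it adopts a compact "bird's nest" conformation
in which two autoinhibitory modules flanking the A1 domain — N′AIM
(residues 1238–1271) and C′AIM (residues 1459–1493) — together with
attached glycans occlude the binding site for the platelet receptor
GPIbα. Elevated shear unfurls the molecule and exposes the site
(*mechano-presentation*). `vwfshield` implements the analysis used to
quantify this process from molecular-dynamics trajectories, and a seeded
coarse-grained simulator that provides a complete ground truth against
which every stage of the analysis is tested.

## The accessibility score

The central quantity is a per-frame steric-clash count. A static
receptor-complex reference (in the VWF system, the A1–GPIbα co-crystal)
is superposed onto every trajectory frame by a least-squares (Kabsch) fit
of the heavy atoms of a rigid anchor region (A1 residues 1290–1430). The
transformed receptor heavy atoms (residues 1–265) are then compared with
the heavy atoms of each dynamic shielding region — N′AIM, C′AIM, the
D′D3 region, or arbitrary construct regions — plus the atoms of any
glycan whose minimum heavy-atom distance to the region is within 0.5 nm.
Every unordered atom pair closer than 0.30 nm counts as one clash:

> clash(region, t) = #{ (i, j) : i ∈ receptor, j ∈ region ∪ assigned
> glycans, ‖x_i(t) − x_j(t)‖ < 0.30 nm }

A shielded epitope produces many clashes with the superposed receptor
footprint; as force removes the arms the count decays to zero, so the
series is a direct, structure-based readout of epitope accessibility.

Two conventions here were genuinely open and are fixed as follows:

* **Cutoff inclusivity.** We use a strict `<` 0.30 nm comparison (a
  closed cutoff is available as `inclusive = TRUE`); the two differ only
  on measure-zero geometries.
* **Glycan assignment.** Assignment of glycans to regions is re-evaluated
  *per frame* by default (`glycan_assignment = "per_frame"`), because
  glycans travel with the arms they decorate; a one-time initial-frame
  assignment is available and gives identical results whenever the
  glycan–region association is stable.

`normalized_clash()` rescales each region's series into [0, 1] by its own
maximum (mode `"max"`, the default) or by its initial value. For
cross-construct comparison, `construct_compare()` instead normalises all
constructs by one common maximum so that values stay in [0, 1] *and* the
ranking equals the raw-mean ranking; a per-construct maximum would not
preserve monotonicity when one construct's regions are a superset of
another's.

## Interaction criteria

Hydrogen bonds and salt bridges follow fixed geometric criteria:

* **Hydrogen bond**: donor–acceptor distance ≤ 0.35 nm *and*
  donor–hydrogen–acceptor angle ≥ 150°. Donor atoms are N, NE, ND1, NE2,
  NH1, NH2, OG, OG1, OH; acceptors are O, OD1, OD2, OE1, OE2, OG, OG1,
  OH. When the trajectory carries hydrogens, the true D–H–A angle is used
  (each hydrogen is attached to its nearest donor-capable heavy atom
  within 0.12 nm, so no bond table is required). When hydrogens are
  absent, the angle at the donor formed by its nearest heavy-atom
  antecedent, the donor and the acceptor approximates the D–H–A angle and
  the record is flagged `approximate`. Because OG/OG1/OH appear in both
  atom lists a pair could be found in both directions; records are
  de-duplicated by unordered atom pair.
* **Salt bridge**: any Lys NZ or Arg NE/NH1/NH2 nitrogen within ≤ 0.35 nm
  (inclusive) of any Asp OD1/OD2 or Glu OE1/OE2 oxygen.

Contact records from replicate runs are concatenated after frame
reindexing; a residue pair's frequency is the fraction of combined frames
in which it forms either contact, and only pairs present in **at least
10%** of combined frames (boundary inclusive) survive the persistence
filter used for heatmaps.

For intramolecular hydrogen-bond counting the whole module serves as both
groups with an exclusion of |Δresnum| < 2, so trivially adjacent residues
never count; the exclusion width is a parameter.

## Structural descriptors

* **RMSD** — each frame is fitted to the reference (frame 1 by default)
  on backbone (N, CA, C, O) heavy atoms and measured over the same
  selection. Fit and measure selections are both configurable, so a
  fit-all/measure-backbone variant is one argument away.
* **RMSF** — Cα fluctuations about the time-average structure; frames are
  first fitted to frame 1, the average is formed, frames are re-fitted to
  the average, and the average is recomputed — the conventional two-pass
  scheme.
* **Radius of gyration** — mass-weighted by default (element masses from
  an internal table), with an unweighted variant.
* **SASA** — Shrake–Rupley quadrature with probe radius 0.14 nm, Bondi
  van der Waals radii and 960 deterministic golden-spiral points per
  atom; an isolated atom reproduces its analytic sphere area within 1%.
  SASA is the one quadratic-cost descriptor; `sasa_series()` therefore
  takes a frame stride.
* **Window statistics** — half-open windows [t0, t1); the defaults mirror
  the early (0–100 ns) and late (400–500 ns) stages of a 500-ns run.
* **Smoothing** — Savitzky–Golay, default window 51 frames and polynomial
  order 3. The ends use the filter's asymmetric end-window polynomial
  fits, so polynomials up to the filter order are reproduced exactly
  everywhere; when a series is shorter than the preferred window,
  `clamp_savgol_window()` shrinks it to the largest valid odd window.

## Flow calibration and steered pulls

The Newtonian relation τ = μγ̇ with μ = 6.93 × 10⁻⁴ Pa·s (water at
310 K) converts wall shear stress to shear rate: 70 dyn/cm² ≈ 1.01 × 10⁴
s⁻¹ (arterial baseline) and 1280 dyn/cm² ≈ 1.85 × 10⁵ s⁻¹ (pathological
peak). The nominal rate of a constant-velocity pull is γ̇ = v/L; at
v = 0.01 nm/ps over a 150-nm box this is 6.7 × 10⁷ s⁻¹, about 360× the
pathological rate. These constants live in `flow_params()` and the
conversions in `shear_rate_from_stress()`, `nominal_shear_rate()` and
`acceleration_factor()`; such acceleration is deliberate and standard for
reaching unfolding events at simulation timescales — the regime is
calibrated to rank kinetic stability, not to reproduce physiological
rates.

Force–extension analysis converts spring forces (1 kJ mol⁻¹ nm⁻¹ =
1.66054 pN) and reads two-column pull logs (xvg comment lines skipped).
"Rupture force is the peak force prior to detachment" is verbal, so
detachment needs an operational definition: the first frame where the
force falls below `drop_fraction` (default 0.5) of the running peak and
stays there for `sustain_frames` (default 10) consecutive frames. Both
knobs are exposed; an all-events mode restarts the scan after each
detachment.

## The synthetic test-bed

`build_toy_mechanomodule()` constructs a coarse bead model that is **an
analysis test-bed, not a physical MD engine**: drag, noise and stiffness
are dimensionless knobs tuned only so the detectors' geometric thresholds
are meaningfully exercised. It emulates:

* a static core carrying the alignment anchor (residues 1272–1458, with
  1290–1430 as the rigid anchor), two arms (1238–1271, 1459–1493) and a
  restrained D′D3 stub (764–823) — ~316 pseudo-residues;
* a pseudo-receptor reference (residues 1–265) whose probe atoms are
  planted at known distances from arm and glycan atoms: below the clash
  cutoff (0.25 nm), inside the glycan band (0.40 nm) and beyond it
  (0.60 nm);
* planted donor–hydrogen–acceptor triplets and Lys/Glu cation–anion pairs
  between arm and core residues, including decoys that fail exactly one
  criterion (distance 0.40 nm; angle 140°);
* N- and O-linked glycan pseudo-atoms on arm residues, one deliberately
  placed outside the 0.5-nm assignment band.

Each planted feature occupies its own residue (disjoint residue classes
per arm), so features never interfere. `simulate_uncoiling()` performs
seeded overdamped updates in which every bead relaxes toward a target
plus Gaussian noise; uncoiling is realised by switching arm targets from
docked to retracted positions. In flow mode the release schedule is
planted: the C-terminal arm releases first (frames ~30–70 at unit flow
strength), the distal/flanking part of the N-terminal arm next (~90–140)
and its proximal part last (~155–185), encoding the finding that
N-terminal shielding — and its proximal segment in particular — is the
final barrier. Flow strength scales the schedule and the drift speed, so
stronger flow uncoils earlier and extends further; zero strength reduces
to the equilibrium ensemble. In steered mode a harmonic spring
(1000 kJ mol⁻¹ nm⁻²) between the terminal Cα sites ramps until the force
crosses a planted threshold, at which point the C-terminal arm lets go and
the pulled terminus tracks the restraint; "glycosylated" runs raise that
threshold by ×1.3 to emulate glycan drag, which makes their rupture force
strictly larger.

The `GroundTruthLog` is measured every frame by direct arithmetic over
*complete* candidate sets (all donor × acceptor, cation × anion and
receptor × region pairs) — deliberately not by calling the analysis-path
detectors — so it is simultaneously independent of, and exhaustively
comparable with, the pipeline's output. Coordinates are quantised to PDB
precision (10⁻⁴ nm) during simulation, so a fixture exported to
multi-model PDB and re-read reproduces the log bit-exactly.

What the toy does **not** emulate: atomistic energetics, solvent, real
glycan chemistry, secondary structure, or realistic force scales. Passing
tests therefore demonstrate the *correctness of the measurement
machinery* (detectors, superposition, counting, filtering, bookkeeping)
under known truth, not the biology of any real trajectory — real
conclusions still require real simulations, to which the same pipeline
applies unchanged.

## Numerical choices

* Internal unit is nm; PDB files are Å at the boundary with a single
  conversion site. Author residue numbering is preserved verbatim.
* Altloc handling keeps the highest-occupancy conformer, ties broken by
  altloc letter.
* Kabsch superposition uses the SVD construction with the determinant
  correction for proper rotations; selections with fewer than three pairs
  or collinear geometry raise a degenerate-superposition error. Anchor
  matching between reference and topology is by (residue number, atom
  name) intersection with a floor of 100 matched atoms by default.
* Per-frame anchor fit RMSD above 0.5 nm (configurable) triggers a
  warning — a large value means the "rigid" anchor deformed and the clash
  count is no longer meaningful.
* Construct presets: D′D3 = 764–1237, flanking peptide = 1238–1267,
  proximal N′AIM = 1268–1271; ranges are configuration, not code
  constants.

## Problem sizes

The shipped analyses and tests use the generator's defaults: ~371 atoms,
200-frame runs (0.1 ns/frame for flow and steered runs; 2.5 ns/frame for
the equilibrium run so that the early/late windows 0–100 ns and
400–500 ns apply), three replicates for flow and steered conditions, and
20 seeds for the across-seed ranking properties. These sizes keep every
analysis deterministic and fast while exercising all thresholds; they are
the package's chosen study conditions, not tuned quantities.

## Limitations

* Trajectory input is multi-model PDB and DCD; XTC is not read (no R
  reader available), and mmCIF, PBC unwrapping and bond-topology
  perception are out of scope.
* Contact detection covers hydrogen bonds and salt bridges only — no
  π–cation, hydrophobic or water-mediated contacts, and no energetic
  scoring.
* The clash score is a geometric accessibility proxy; it does not predict
  binding free energies or dissociation constants, only their ordering
  under the shielding hypothesis.
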