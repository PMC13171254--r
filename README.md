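# vwfshield

Steric-shielding and mechano-presentation analysis for force-unfolded
protein modules, built around the von Willebrand factor (VWF)
mechanomodule (residues 764–1873: D′D3–A1–A2–A3).

VWF conceals its platelet-receptor (GPIbα) binding site inside a compact
"bird's nest": two autoinhibitory arms flanking the A1 domain — N′AIM
(residues 1238–1271) and C′AIM (1459–1493) — plus attached glycans occlude
the interface, and shear flow unmasks it. `vwfshield` is for structural
bioinformaticians who want to quantify that unmasking from MD
trajectories:

* **Accessibility score** — a static receptor complex is superposed onto
  every frame via a rigid A1 anchor (heavy atoms of residues 1290–1430,
  Kabsch fit), and heavy-atom pairs with ‖x_i − x_j‖ < 3.0 Å between the
  transformed receptor (GPIbα residues 1–265) and each dynamic shielding
  region (arms, D′D3, construct regions, plus any glycan within 5 Å of the
  region) are counted per frame (`clash_scan()`, `normalized_clash()`,
  `construct_compare()`).
* **Interactions** — hydrogen bonds (donor–acceptor ≤ 3.5 Å and
  D–H–A angle ≥ 150°) and salt bridges (Lys NZ / Arg NE,NH1,NH2 to
  Asp OD1,OD2 / Glu OE1,OE2 within ≤ 3.5 Å), per-frame time series,
  replicate concatenation and contact-frequency maps with the ≥10%
  persistence filter (`detect_hbonds()`, `contact_frequency_map()`).
* **Descriptors** — RMSD, per-residue Cα RMSF, radius of gyration,
  Shrake–Rupley SASA, window statistics, probability densities,
  Savitzky–Golay smoothing.
* **Force analysis** — force–extension profiles (1 kJ mol⁻¹ nm⁻¹ =
  1.66054 pN), rupture force as the peak prior to detachment, and flow
  calibration via the Newtonian relation τ = μγ̇ and the nominal rate
  γ̇ = v/L (`shear_rate_from_stress()`, `acceleration_factor()`).
* **Synthetic test-bed** — a seeded coarse-grained mechanomodule with
  planted contacts, clashes and glycans and a complete per-frame
  ground-truth log (`build_toy_mechanomodule()`, `simulate_uncoiling()`,
  `export_fixture()`), so every analysis stage is verified against known
  truth.

## Worked example

```r
library(vwfshield)

# map simulated pulling onto physiological shear
shear_rate_from_stress(dyn_cm2_to_pa(70))    # 10101.01  (arterial, 1/s)
shear_rate_from_stress(dyn_cm2_to_pa(1280))  # 184704.2  (pathological)
acceleration_factor(0.01, 150, 128)          # 360.9375

# a seeded flow-driven uncoiling run with ground truth
model <- build_toy_mechanomodule(seed = 1)
sim   <- simulate_uncoiling(model, sim_config("flow", seed = 201))

cfg <- clash_config(shield_regions = model$regions[c("naim", "caim")])
nc  <- normalized_clash(clash_scan(sim$trajectory, model$reference,
                                   cfg, model$glycans))
nc$means
#>      naim      caim
#> 0.6507143 0.1862500
```

The N-terminal arm's mean normalised clash (0.651) far exceeds the
C-terminal arm's (0.186): C′AIM shielding collapses early in the run while
N′AIM keeps obstructing the receptor footprint — the signature of its
dominant autoinhibitory role. Ranking deletion constructs on the same
trajectory reproduces the accessibility ordering:

```r
cc <- construct_compare(sim$trajectory, model$reference,
                        default_construct_presets(), clash_config(),
                        model$glycans)
cc$construct[order(cc$rank)]
#> "dPro" "dD_D3" "dD_D3OG-" "dD_D3NFP-"
```

i.e. deleting D′D3 together with the N-terminal flanking peptide
(`dD_D3NFP-`) exposes the receptor site most. A steered pull between the
terminal Cα sites (residues 1238 and 1493) ruptures the C-terminal arm at
~675 pN without glycan drag and ~877 pN with it (×1.30), while the
N-terminal arm keeps clashing with the receptor to the end of the run.

The `analysis/` directory contains the full narrative as numbered
drivers — `01_simulate.R` … `06_flow_calibration.R` — each a thin script
over these functions that writes its tables under `results/` (fixtures go
under `scratch/`).

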