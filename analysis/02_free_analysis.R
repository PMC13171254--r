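#!/usr/bin/env Rscript
# Equilibrium (free) descriptor analysis of the compact "bird's nest"
# ensemble: RMSD, radius of gyration, SASA, intramolecular hydrogen-bond
# count, per-residue RMSF, arm-to-core interactions and the steric-clash
# baseline, with early (0-100 ns) and late (400-500 ns) window statistics.

suppressMessages(library(vwfshield))

model <- build_toy_mechanomodule(seed = 1)
free <- simulate_uncoiling(model, sim_config("free", seed = 101))

res <- run_free_analysis(
  free$trajectory, reference = model$reference, regions = model$regions,
  glycans = model$glycans, out_dir = "results/02_free",
  sasa_stride = 5,
  clash_cfg = clash_config(shield_regions = model$regions[c("naim", "caim")],
                           smooth_window = 21))

cat("Window statistics (early R1 vs late R5):\n")
print(res$window_stats)

rf <- res$rmsf
arm <- rf$resnum %in% c(1238:1271, 1459:1493)
cat(sprintf("\nMean RMSF: arms %.3f nm vs core %.3f nm (arms fluctuate more)\n",
            mean(rf$rmsf[arm]), mean(rf$rmsf[!arm])))
cat(sprintf("Mean AIM-A1 contacts per frame: %.1f (stable at equilibrium)\n",
            mean(res$interactions$total)))
cat(sprintf("Mean baseline clash (naim, caim): %.1f, %.1f - the receptor site stays occluded without force\n",
            mean(res$clash$per_region[, "naim"]),
            mean(res$clash$per_region[, "caim"])))
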