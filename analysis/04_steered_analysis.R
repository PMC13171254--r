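#!/usr/bin/env Rscript
# Steered constant-velocity pulls between the terminal C-alpha sites
# (residues 1238 and 1493): force-extension profiles, rupture forces, and
# the glycan-drag contrast (planted extra drag raises the force needed to
# free the C-terminal arm).

suppressMessages(library(vwfshield))

model <- build_toy_mechanomodule(seed = 1)
serial_of <- function(res) {
  a <- model$structure$atoms
  a$serial[a$resnum == res & a$atom_name == "CA"]
}

run_cond <- function(gly, out_dir) {
  runs <- lapply(1:3, function(k) {
    sim <- simulate_uncoiling(model, sim_config("steered", seed = 300 + k,
                                                glycosylated = gly))
    list(traj = sim$trajectory, force_log = sim$log$pull_force_kj)
  })
  run_steered_analysis(runs, serial_of(1238), serial_of(1493), out_dir,
                       reference = model$reference, regions = model$regions,
                       glycans = if (gly) model$glycans else list())
}

bare <- run_cond(FALSE, "results/04_steered_bare")
glyc <- run_cond(TRUE, "results/04_steered_glycosylated")

cat("Rupture events (bare):\n"); print(bare$events)
cat("Rupture events (glycosylated):\n"); print(glyc$events)
ratio <- mean(glyc$events$peak_force) / mean(bare$events$peak_force)
cat(sprintf("\nMean rupture force: %.0f pN bare vs %.0f pN glycosylated (x%.2f)\n",
            mean(bare$events$peak_force), mean(glyc$events$peak_force),
            ratio))
cat("After the C-terminal arm ruptures its clashes vanish, while the",
    "N-terminal arm keeps shielding the receptor site under tension:\n")
cs <- bare$clash
cat(sprintf("  late-run mean clash: naim %.2f, caim %.2f\n",
            mean(tail(cs$per_region[, "naim"], 40)),
            mean(tail(cs$per_region[, "caim"], 40))))
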