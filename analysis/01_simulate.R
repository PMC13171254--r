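#!/usr/bin/env Rscript
# Build the coarse-grained mechanomodule test-bed and simulate the three
# study conditions (equilibrium, flow-driven uncoiling in triplicate, and
# constant-velocity steered pulls with and without glycan drag). Fixtures
# (multi-model PDB + config + ground-truth JSON) go under scratch/; a small
# inventory table goes under results/.

suppressMessages(library(vwfshield))

fix_root <- "scratch/fixtures"
dir.create("results", showWarnings = FALSE)
model <- build_toy_mechanomodule(seed = 1)
print(model)

inventory <- list()
note <- function(name, sim) {
  inventory[[length(inventory) + 1]] <<- data.frame(
    run = name, mode = sim$log$mode, seed = sim$log$seed,
    n_frames = sim$log$n_frames,
    n_contacts_frame1 = sum(sim$log$contacts$frame == 1),
    mean_total_clash = mean(rowSums(
      sim$log$clash_counts[, c("naim", "caim")])),
    final_extension_nm = tail(sim$log$extension, 1))
}

free <- simulate_uncoiling(model, sim_config("free", seed = 101))
export_fixture(free$trajectory, free$log, model, file.path(fix_root, "free"))
note("free", free)

for (k in 1:3) {
  flow <- simulate_uncoiling(model, sim_config("flow", seed = 200 + k))
  export_fixture(flow$trajectory, flow$log, model,
                 file.path(fix_root, paste0("flow_rep", k)))
  note(paste0("flow_rep", k), flow)
}

for (k in 1:3) {
  for (gly in c(FALSE, TRUE)) {
    st <- simulate_uncoiling(model, sim_config("steered", seed = 300 + k,
                                               glycosylated = gly))
    tag <- paste0("steered_", if (gly) "glyco" else "bare", "_rep", k)
    export_fixture(st$trajectory, st$log, model, file.path(fix_root, tag))
    note(tag, st)
  }
}

inventory <- do.call(rbind, inventory)
write.csv(inventory, "results/01_simulation_inventory.csv",
          row.names = FALSE)
print(inventory)
cat("\nFixtures written under", fix_root,
    "- the flow replicates start fully shielded (planted clashes on both",
    "arms) and uncoil on the seeded schedule; the C-terminal arm clears",
    "first, the proximal N-terminal arm last.\n")
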