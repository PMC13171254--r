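#!/usr/bin/env Rscript
# Construct-resolved accessibility: evaluate deletion constructs (full
# shielding, D'D3 deleted, D'D3+flanking-peptide deleted, D'D3 deleted
# without O-glycans) on the same flow trajectory and rank their mean
# normalised clash - the simulated analogue of comparing receptor-binding
# affinities across constructs.

suppressMessages(library(vwfshield))

model <- build_toy_mechanomodule(seed = 1)
sim <- simulate_uncoiling(model, sim_config("flow", seed = 201))

cc <- construct_compare(sim$trajectory, model$reference,
                        default_construct_presets(), clash_config(),
                        model$glycans)
dir.create("results/05_constructs", recursive = TRUE, showWarnings = FALSE)
write.csv(cc, "results/05_constructs/construct_table.csv", row.names = FALSE)
print(cc)
cat("\nRecovered accessibility ranking (most shielded first):",
    paste(cc$construct[order(cc$rank)], collapse = " > "), "\n")
cat("Planted ranking from the ground-truth log:               ",
    paste(sim$log$construct_order, collapse = " > "), "\n")
cat("Deleting D'D3 plus the flanking peptide exposes the receptor site",
    "most, mirroring the construct with the highest binding affinity.\n")
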