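#!/usr/bin/env Rscript
# Simulate the full plate study: 2 treatments x 2 plots x 3 plants
# (6 leaves per treatment), 10 bacteria + 10 fungi per leaf with one
# deficient control leaf (5 bacteria), i.e. 115 bacteria + 120 fungi = 235
# isolates. Writes the plate, metadata, layout, and truth files that the
# downstream steps (02-05) read.

library(endoniche)

seed <- 20240901L
out <- "results/sim"

cfg <- sim_config("paper-like", seed = seed)
sim <- simulate_study(cfg)
write_simulated_study(sim, out)

cat("Simulated", nrow(sim$meta), "isolates (",
    sum(sim$meta$kingdom == "Bacteria"), "bacteria,",
    sum(sim$meta$kingdom == "Fungi"), "fungi ) across",
    length(unique(sim$meta$leaf_id)), "leaves\n")
cat("Files written under", out, ": plates.tsv, metadata.tsv, layout.tsv, truth.json\n")
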