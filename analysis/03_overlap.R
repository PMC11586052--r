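#!/usr/bin/env Rscript
# Directional resource niche overlap between sympatric (same-leaf) isolate
# pairs: for each ordered pair (i -> j) and each substrate both use, the
# fraction of j's growth matched by i (capped at 1), averaged over the 95
# substrates. Summarized by pair class (B:B, F:F, B:F, F:B) and treatment.

library(endoniche)

prof <- read_profiles("results/profiles.tsv")
pu <- sympatric_pairs(prof$meta)
cat("Ordered sympatric pairs per class and treatment:\n")
print(pu$counts)

ov <- overlap_table(prof)
write.table(ov, "results/overlap.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
smry <- group_overlap_summary(ov)
write.table(smry, "results/overlap_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(transform(smry, mean = round(mean, 3), sd = round(sd, 3)))

bf <- smry[smry$pair_class == "B:F", ]
fb <- smry[smry$pair_class == "F:B", ]
cat(sprintf("B:F overlap (bacterial pressure on fungi): control %.3f -> NPKu %.3f\n",
            bf$mean[bf$treatment == "control"], bf$mean[bf$treatment == "NPKu"]))
cat(sprintf("F:B overlap (fungal pressure on bacteria): control %.3f -> NPKu %.3f\n",
            fb$mean[fb$treatment == "control"], fb$mean[fb$treatment == "NPKu"]))
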