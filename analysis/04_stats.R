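#!/usr/bin/env Rscript
# Inference battery on the phenotyped isolates:
#  - evenness and overlap treatment comparisons (Shapiro-Wilk-routed
#    Welch t / Wilcoxon) corrected as one Benjamini-Hochberg family;
#  - Bray-Curtis dissimilarity of carbon-use profiles; PERMANOVA
#    (kingdom x treatment, 999 permutations); PERMDISP (9999 permutations)
#    with Tukey HSD;
#  - kingdom x treatment mixed models of NW (Poisson), TG and GE
#    (log-Gaussian) with a leaf random intercept and LS-means contrasts.

library(endoniche)

seed <- 20240904L
prof <- read_profiles("results/profiles.tsv")
mt <- read.delim("results/metrics.tsv")
ov <- read.delim("results/overlap.tsv")

grp <- function(col, k, tr) mt[[col]][mt$kingdom == k & mt$treatment == tr]
ovg <- function(cls, tr) ov$omega_bar[ov$pair_class == cls & ov$treatment == tr]
fam <- list(
  evenness_B = list(grp("J", "Bacteria", "control"), grp("J", "Bacteria", "NPKu")),
  evenness_F = list(grp("J", "Fungi", "control"), grp("J", "Fungi", "NPKu")),
  overlap_BF = list(ovg("B:F", "control"), ovg("B:F", "NPKu")),
  overlap_FB = list(ovg("F:B", "control"), ovg("F:B", "NPKu")),
  overlap_BB = list(ovg("B:B", "control"), ovg("B:B", "NPKu")),
  overlap_FF = list(ovg("F:F", "control"), ovg("F:F", "NPKu")))
tests <- comparison_family(fam)
write.table(tests, "results/group_tests.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("Treatment comparisons (BH-adjusted within one family):\n")
print(tests[, c("comparison", "test_used", "p_value", "p_adjusted")])

d <- bray_curtis(prof)
write_phylip_square(d, "results/bray_curtis.phylip")
pm <- permanova_terms(d, prof$meta, ~ kingdom * treatment,
                      permutations = 999, seed = seed)
write.table(pm, "results/permanova.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nPERMANOVA on Bray-Curtis carbon-use dissimilarity:\n")
print(transform(pm, R2 = round(R2, 3), F = round(F, 2)))

grp4 <- interaction(prof$meta$kingdom, prof$meta$treatment)
disp <- dispersion_test(d, grp4, permutations = 9999, seed = seed + 1L)
cat("\nPERMDISP across kingdom x treatment groups: F =",
    round(disp$F, 2), ", p =", disp$p_value, "\n")
print(round(disp$group_means, 3))
write.table(disp$tukey, "results/permdisp_tukey.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nMixed models (leaf random intercept), within-kingdom treatment contrasts:\n")
for (resp in c("NW", "TG", "GE")) {
  mm <- suppressWarnings(metric_model(mt, resp))
  for (k in c("Bacteria", "Fungi")) {
    ctr <- treatment_contrast(mm, k)
    cat(sprintf("  %-2s %-8s control - NPKu: estimate %+.3f (link scale), p = %.4g\n",
                resp, k, ctr$estimate, ctr$p_value))
  }
}
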