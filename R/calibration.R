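#' Type-I-error calibration of the permutation battery under the null preset
#'
#' Simulates many small studies from the `"null"` preset (no treatment
#' effects) and measures the rejection rate at `alpha` of (i) PERMANOVA on
#' the treatment term, (ii) PERMDISP across treatments, and (iii) the
#' normality-routed two-sample router on carbon-use evenness. Calibration
#' studies drop the leaf random effect and the deficient leaf so that
#' isolates are exchangeable under the null -- the property the
#' row-permutation tests assume; see the methods vignette.
#'
#' @param nrep Number of simulated studies (default 500).
#' @param seed Master seed; study r uses seed + r.
#' @param fungi_per_leaf Isolates per leaf in the calibration design
#'   (default 10; 2 leaves per treatment, fungi only, 40 isolates --
#'   large enough that the median-based dispersion test is out of its
#'   small-sample conservative regime).
#' @param permutations Permutations per test (default 199).
#' @param alpha Nominal level (default 0.05).
#' @return Named numeric vector of rejection rates: `permanova`, `permdisp`,
#'   `two_sample`.
#' @export
null_calibration <- function(nrep = 500, seed = 1L, fungi_per_leaf = 10L,
                             permutations = 199, alpha = 0.05) {
  cfg0 <- sim_config("null", seed = 1L,
                     plots_per_treatment = 1L, plants_per_plot = 2L,
                     bacteria_per_leaf = 0L, fungi_per_leaf = fungi_per_leaf,
                     deficient_leaf = NULL, leaf_sdlog = 0)
  hits <- c(permanova = 0, permdisp = 0, two_sample = 0)
  base <- (as.numeric(seed) %% 20000) * 100000  # distinct seed block per master seed
  for (r in seq_len(nrep)) {
    cfg <- cfg0
    cfg$seed <- as.integer(base + r)
    sim <- simulate_study(cfg)
    prof <- correct_and_threshold(sim$plates)
    d <- bray_curtis(prof)
    meta <- prof$meta
    pa <- permanova_terms(d, meta, ~ treatment, permutations = permutations)
    pd <- dispersion_test(d, meta$treatment, permutations = permutations)
    J <- evenness(prof)
    ts <- two_sample_auto(J[meta$treatment == "control"],
                          J[meta$treatment == "NPKu"])
    hits <- hits + c(pa$p_value[1] <= alpha, pd$p_value <= alpha,
                     ts$p_value <= alpha)
  }
  hits / nrep
}

#' Direction recovery of the planted effects at study size
#'
#' Simulates `nrep` full studies from the `"paper-like"` preset and, per
#' replicate, runs [effect_direction_report()]. An effect with a planted
#' direction is "recovered" when its test is significant at `alpha` in the
#' planted direction; a null effect (the bacterial metrics) is recovered
#' when its test is nonsignificant.
#'
#' @param nrep Number of replicates (default 50).
#' @param seed Master seed; replicate r uses seed + r.
#' @param alpha Significance level (default 0.05).
#' @return data.frame: `effect`, `planted` (+1 control higher, -1 NPKu
#'   higher, 0 none), `recovery_rate`.
#' @export
direction_recovery <- function(nrep = 50, seed = 1L, alpha = 0.05) {
  planted <- c(fungal_NW = 1, fungal_TG = 1, fungal_evenness = 1,
               overlap_BF = -1, overlap_FB = 1,
               bacterial_NW = 0, bacterial_TG = 0, bacterial_evenness = 0)
  hits <- stats::setNames(numeric(length(planted)), names(planted))
  base <- (as.numeric(seed) %% 20000) * 100000
  for (r in seq_len(nrep)) {
    sim <- simulate_study(sim_config(seed = as.integer(base + 50000 + r)))
    prof <- correct_and_threshold(sim$plates)
    rep1 <- suppressWarnings(effect_direction_report(prof))
    for (nm in names(planted)) {
      row <- rep1[rep1$effect == nm, ]
      ok <- if (planted[nm] == 0) {
        row$p_value >= alpha
      } else {
        row$p_value < alpha && row$direction == planted[nm]
      }
      hits[nm] <- hits[nm] + ok
    }
  }
  data.frame(effect = names(planted), planted = unname(planted),
             recovery_rate = unname(hits) / nrep,
             stringsAsFactors = FALSE)
}
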