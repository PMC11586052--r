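#' Kingdom-by-treatment mixed model of a carbon-use metric
#'
#' Fits the metric against a kingdom x treatment fixed-effect interaction
#' with a random intercept for leaf. Niche width (a count) is modelled as
#' Poisson with log link; total growth and growth efficiency are
#' log-transformed and modelled as Gaussian (rows with nonpositive or
#' undefined values are dropped with a warning). Estimated marginal means
#' per kingdom x treatment cell and all pairwise contrasts are returned. A
#' singular random-effect fit falls back to the fixed-effects-only model,
#' recorded in `warnings`.
#'
#' @param metrics data.frame from [metrics_table()].
#' @param response One of `"NW"`, `"TG"`, `"GE"`.
#' @return List: `model`, `emmeans` (data.frame of cell means), `contrasts`
#'   (data.frame of pairwise contrasts with p values), `family`,
#'   `warnings` (character).
#' @export
metric_model <- function(metrics, response = c("NW", "TG", "GE")) {
  response <- match.arg(response)
  dat <- metrics
  dat$kingdom <- factor(dat$kingdom, KINGDOMS)
  dat$treatment <- factor(dat$treatment, TREATMENTS)
  for (tr in TREATMENTS) {
    nl <- length(unique(dat$leaf_id[dat$treatment == tr]))
    if (nl < 2) stop("need at least 2 leaves per treatment (", tr, " has ", nl, ")")
  }
  warns <- character()
  if (response == "NW") {
    dat$y <- dat$NW
    dat <- dat[!is.na(dat$y), ]
    fam <- "poisson"
  } else {
    dat$y <- dat[[response]]
    bad <- is.na(dat$y) | dat$y <= 0
    if (any(bad)) {
      warns <- c(warns, paste0("dropped ", sum(bad),
                               " rows with nonpositive or undefined ", response))
      warning(warns[length(warns)])
      dat <- dat[!bad, ]
    }
    dat$y <- log(dat$y)
    fam <- "log-gaussian"
  }
  fit <- withCallingHandlers({
    if (fam == "poisson") {
      lme4::glmer(y ~ kingdom * treatment + (1 | leaf_id), data = dat,
                  family = stats::poisson())
    } else {
      lme4::lmer(y ~ kingdom * treatment + (1 | leaf_id), data = dat)
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) {
    warns <<- c(warns, conditionMessage(m))
    invokeRestart("muffleMessage")
  })
  if (lme4::isSingular(fit)) {
    warns <- c(warns, "singular random-effect fit; falling back to fixed effects only")
    fit <- if (fam == "poisson") {
      stats::glm(y ~ kingdom * treatment, data = dat, family = stats::poisson())
    } else {
      stats::lm(y ~ kingdom * treatment, data = dat)
    }
  }
  emm <- emmeans::emmeans(fit, ~ kingdom * treatment)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  # the one pre-specified treatment contrast within each kingdom, unadjusted
  emm_k <- emmeans::emmeans(fit, ~ treatment | kingdom)
  ctr_k <- as.data.frame(emmeans::contrast(emm_k, method = "pairwise",
                                           adjust = "none"))
  list(model = fit,
       emmeans = as.data.frame(emm),
       contrasts = as.data.frame(ctr),
       treatment_contrasts = ctr_k,
       family = fam,
       warnings = warns)
}

#' Within-kingdom treatment contrast from a metric model
#'
#' Convenience accessor: the control vs NPKu contrast estimate and
#' (unadjusted) p value for one kingdom, on the model's link scale.
#'
#' @param mm Result of [metric_model()].
#' @param kingdom `"Bacteria"` or `"Fungi"`.
#' @return data.frame row: `estimate`, `p_value`.
#' @export
treatment_contrast <- function(mm, kingdom = c("Fungi", "Bacteria")) {
  kingdom <- match.arg(kingdom)
  ctr <- mm$treatment_contrasts
  row <- ctr[ctr$kingdom == kingdom & ctr$contrast == "control - NPKu", ]
  if (nrow(row) != 1) stop("treatment contrast not found for ", kingdom)
  data.frame(estimate = row$estimate, p_value = row$p.value)
}
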