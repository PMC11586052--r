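#' Simulation configuration for a synthetic plate study
#'
#' Builds a configuration emulating the field design: 2 treatments x 2 plots
#' x 3 plants (6 leaves per treatment), 10 bacterial and 10 fungal isolates
#' per leaf, with one deficient control leaf carrying only 5 bacteria
#' (235 isolates in total). Kingdom-level mean ODs, per-kingdom treatment
#' multipliers, substrate usage probabilities, and evenness-shaping Gamma
#' concentrations default to values that reproduce the study's reported
#' group means; see the methods vignette for the calibration.
#'
#' @param preset `"paper-like"` (default; treatment effects as observed in
#'   the study), `"null"` (no treatment effects), or `"strong"` (doubled
#'   effects). Unknown names error.
#' @param seed Integer seed stored in the config; all randomness in
#'   [simulate_study()] derives from it.
#' @param ... Named overrides of any config field.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(preset = "paper-like", seed = 1L, ...) {
  if (!preset %in% c("paper-like", "null", "strong")) {
    stop("unknown preset: ", preset)
  }
  km <- function(b_ctl, b_npk, f_ctl, f_npk) {
    matrix(c(b_ctl, b_npk, f_ctl, f_npk), 2, 2, byrow = TRUE,
           dimnames = list(KINGDOMS, TREATMENTS))
  }
  cfg <- list(
    seed = as.integer(seed),
    preset = preset,
    treatments = TREATMENTS,
    plots_per_treatment = 2L,
    plants_per_plot = 3L,
    bacteria_per_leaf = 10L,
    fungi_per_leaf = 10L,
    # one control leaf yielded only five culturable bacteria
    deficient_leaf = list(treatment = "control", leaf_index = 1L,
                          kingdom = "Bacteria", n = 5L),
    kingdom_mean = c(Bacteria = 0.103, Fungi = 0.245),
    # treatment multipliers on the kingdom mean OD
    treat_mult = km(1.00, 1.01, 1.114, 0.886),
    # marginal per-substrate usage probability
    usage_prob = km(0.85, 0.85, 0.889, 0.823),
    # substrate-level usage structure: shared logit-scale easiness spread
    # (easy substrates are used by nearly everyone, hard ones by few),
    # plus isolate-level logit jitter
    usage_substrate_sd = 1.2,
    usage_isolate_sd = 0.4,
    # Gamma shape governing within-isolate spread of used-substrate ODs
    shape = km(2.6, 2.6, 3.0, 2.1),
    # deterministic per-substrate baseline (relative growth support, mean 1),
    # shared by all isolates; rank-aligned with substrate easiness
    substrate_baseline = local({
      b <- exp(stats::qnorm(stats::ppoints(95)) * 0.67)
      b / mean(b)
    }),
    # multiplicative lognormal heterogeneity
    isolate_sdlog = 0.30,
    leaf_sdlog = 0.05,
    water_mean = 0.05,
    noise_sd = 0.003
  )
  if (preset == "null") {
    cfg$treat_mult[, "NPKu"] <- cfg$treat_mult[, "control"]
    cfg$usage_prob[, "NPKu"] <- cfg$usage_prob[, "control"]
    cfg$shape[, "NPKu"] <- cfg$shape[, "control"]
  } else if (preset == "strong") {
    double_gap <- function(m) {
      m[, "NPKu"] <- m[, "control"] + 2 * (m[, "NPKu"] - m[, "control"])
      m
    }
    cfg$treat_mult <- double_gap(cfg$treat_mult)
    cfg$usage_prob <- double_gap(cfg$usage_prob)
    cfg$shape <- double_gap(cfg$shape)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$plots_per_treatment >= 0, cfg$plants_per_plot >= 0,
            cfg$bacteria_per_leaf >= 0, cfg$fungi_per_leaf >= 0,
            all(cfg$usage_prob >= 0 & cfg$usage_prob <= 1),
            cfg$noise_sd >= 0, all(cfg$shape > 0),
            cfg$usage_substrate_sd >= 0, cfg$usage_isolate_sd >= 0)
  structure(cfg, class = "sim_config")
}

#' The three planted-effect presets
#'
#' @param seed Seed stored in each config.
#' @return Named list of `sim_config`s: `null`, `paper-like`, `strong`.
#' @export
planted_effect_presets <- function(seed = 1L) {
  stats::setNames(
    lapply(c("null", "paper-like", "strong"), sim_config, seed = seed),
    c("null", "paper-like", "strong"))
}

#' Simulate a full plate study
#'
#' For each isolate, per-substrate usage is Bernoulli with an
#' isolate-specific probability (Beta-distributed around the kingdom x
#' treatment value); used-substrate latent ODs are Gamma with mean
#' kingdom mean x treatment multiplier x substrate baseline x leaf and
#' isolate lognormal effects, and shape equal to the evenness
#' concentration. Raw well absorbance is water mean + latent OD + Gaussian
#' read noise; the water well is water mean + noise. Deterministic under
#' the config seed.
#'
#' @param config A `sim_config`.
#' @param layout A `plate_layout` (default the shipped SF-P2 layout).
#' @return List of class `sim_study`: `plates` (a `raw_plates` object),
#'   `meta` (its metadata), `truth` (config echo plus realized latent mean
#'   matrix and the leaf/isolate effects).
#' @export
simulate_study <- function(config = sim_config(), layout = default_layout()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  meta <- design_metadata(config)
  if (nrow(meta) == 0) stop("design has zero isolates")
  nsub <- length(config$substrate_baseline)
  leaf_ids <- unique(meta$leaf_id)
  leaf_eff <- stats::setNames(
    stats::rlnorm(length(leaf_ids), -config$leaf_sdlog^2 / 2, config$leaf_sdlog),
    leaf_ids)
  iso_eff <- stats::rlnorm(nrow(meta), -config$isolate_sdlog^2 / 2,
                           config$isolate_sdlog)
  abs_mat <- matrix(NA_real_, nrow(meta), 96,
                    dimnames = list(meta$isolate_id, layout$wells))
  latent_mean <- matrix(0, nrow(meta), nsub,
                        dimnames = list(meta$isolate_id, NULL))
  sub_wells <- names(layout$substrates)
  # deterministic substrate easiness (logit scale), rank-aligned with the
  # baseline so richer substrates are also more widely usable
  ease <- stats::qnorm(stats::ppoints(nsub)) * config$usage_substrate_sd
  # per-cell logit offsets chosen so the marginal usage probability matches
  # the configured value after averaging over substrates and isolate jitter
  egrid <- stats::qnorm(stats::ppoints(21)) * config$usage_isolate_sd
  offset <- config$usage_prob
  for (k in KINGDOMS) for (tr in config$treatments) {
    p <- config$usage_prob[k, tr]
    offset[k, tr] <- if (p >= 1) Inf else if (p <= 0) -Inf else
      stats::uniroot(function(cc) {
        mean(stats::plogis(outer(ease, egrid + cc, "+"))) - p
      }, c(-20, 20))$root
  }
  for (i in seq_len(nrow(meta))) {
    k <- meta$kingdom[i]; tr <- meta$treatment[i]
    e_i <- if (config$usage_isolate_sd > 0) {
      stats::rnorm(1, 0, config$usage_isolate_sd)
    } else 0
    p_vec <- stats::plogis(ease + offset[k, tr] + e_i)
    used <- stats::runif(nsub) < p_vec
    mu <- config$kingdom_mean[k] * config$treat_mult[k, tr] *
      config$substrate_baseline * leaf_eff[meta$leaf_id[i]] * iso_eff[i]
    shape <- config$shape[k, tr]
    latent <- numeric(nsub)
    if (any(used)) {
      latent[used] <- if (is.finite(shape)) {
        stats::rgamma(sum(used), shape = shape, scale = mu[used] / shape)
      } else mu[used]
    }
    latent_mean[i, used] <- mu[used]
    noise <- if (config$noise_sd > 0) stats::rnorm(96, 0, config$noise_sd) else numeric(96)
    abs_mat[i, layout$water_well] <- config$water_mean + noise[96]
    abs_mat[i, sub_wells] <- config$water_mean + latent + noise[1:95]
  }
  plates <- structure(list(absorbance = abs_mat, meta = meta, layout = layout),
                      class = "raw_plates")
  truth <- list(config = config, leaf_effects = leaf_eff,
                isolate_effects = stats::setNames(iso_eff, meta$isolate_id),
                latent_mean = latent_mean, seed = config$seed)
  structure(list(plates = plates, meta = meta, truth = truth),
            class = "sim_study")
}

# Metadata for the nested design: treatments > plots > plants(leaves) > isolates.
design_metadata <- function(config) {
  rows <- list()
  for (tr in config$treatments) {
    tr_code <- if (tr == "control") "C" else "N"
    leaf_no <- 0L
    for (pl in seq_len(config$plots_per_treatment)) {
      plot_id <- paste0(tr_code, pl)
      for (pp in seq_len(config$plants_per_plot)) {
        leaf_no <- leaf_no + 1L
        leaf_id <- paste0("leaf_", tr_code, leaf_no)
        nb <- config$bacteria_per_leaf
        nf <- config$fungi_per_leaf
        dl <- config$deficient_leaf
        if (!is.null(dl) && dl$treatment == tr && dl$leaf_index == leaf_no) {
          if (dl$kingdom == "Bacteria") nb <- dl$n else nf <- dl$n
        }
        if (nb + nf == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          isolate_id = c(sprintf("%s_B%02d", leaf_id, seq_len(nb)),
                         sprintf("%s_F%02d", leaf_id, seq_len(nf))),
          kingdom = rep(KINGDOMS, c(nb, nf)),
          treatment = tr, leaf_id = leaf_id, plot_id = plot_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    stop("design has zero isolates")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated study to the plate-table file dialects
#'
#' Emits `plates.tsv` (wide), `metadata.tsv`, `layout.tsv`, and
#' `truth.json` (config echo and seed) under `dir`. Identical seeds give
#' byte-identical files.
#'
#' @param sim A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- sim$plates$absorbance
  odc <- apply(mat, 2, function(v) sprintf("%.17g", v))
  if (is.null(dim(odc))) odc <- matrix(odc, nrow = 1)
  plates <- data.frame(isolate_id = rownames(mat), odc,
                       stringsAsFactors = FALSE, check.names = FALSE)
  colnames(plates) <- c("isolate_id", colnames(mat))
  utils::write.table(plates, file.path(dir, "plates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  layout <- sim$plates$layout
  lay <- data.frame(well = layout$wells,
                    substrate = ifelse(layout$wells == layout$water_well,
                                       "water",
                                       layout$substrates[layout$wells]),
                    is_water = as.integer(layout$wells == layout$water_well))
  utils::write.table(lay, file.path(dir, "layout.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- unclass(sim$truth$config)
  truth$substrate_baseline <- NULL  # re-derivable from preset fields
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate a distance matrix correlated with a reference matrix
#'
#' Draws a synthetic "phylogenetic" distance matrix whose off-diagonal
#' entries have Pearson correlation approximately `r` with the reference
#' (e.g. a carbon-use dissimilarity), for exercising Mantel and
#' regression recovery. Entries are shifted to be nonnegative; the result
#' is symmetric with zero diagonal but not necessarily metric.
#'
#' @param d Reference `dist`.
#' @param r Target correlation in [-1, 1].
#' @param seed Integer seed.
#' @return A `dist` with the same labels.
#' @export
simulate_correlated_distance <- function(d, r, seed = 1L) {
  stopifnot(abs(r) <= 1)
  set.seed(seed)
  v <- as.vector(d)
  z1 <- as.vector(scale(v))
  z2 <- stats::rnorm(length(v))
  z2 <- as.vector(scale(stats::resid(stats::lm(z2 ~ z1))))
  z <- r * z1 + sqrt(1 - r^2) * z2
  out <- d
  out[] <- z - min(z) + 0.01
  out
}
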