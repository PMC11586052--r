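#' Run the full analysis end to end
#'
#' Stages, in order: ingest -> metrics -> evenness -> overlap -> group
#' comparisons (+ BH) -> Bray-Curtis -> PERMANOVA/PERMDISP -> phylogenetic
#' distances -> Mantel + dissimilarity regression -> kingdom x treatment
#' models. Every stage writes a delimited table under `out_dir`; a manifest
#' records the configuration, seeds, and package version. Any stage failure
#' aborts with the stage name; tables already written are retained next to a
#' `FAILED` marker. Phylogenetic stages are skipped with a logged warning
#' when no alignments or distance matrices are supplied.
#'
#' @param plates_path,metadata_path,layout_path Input files (see
#'   [read_plates()]); `layout_path = NULL` uses the shipped SF-P2 layout.
#' @param out_dir Output directory (created).
#' @param alignments Optional named list of FASTA paths per kingdom, e.g.
#'   `list(Bacteria = "16s.fasta", Fungi = "its.fasta")`.
#' @param distances Optional named list of PHYLIP square matrix paths per
#'   kingdom (used instead of alignments when given).
#' @param threshold Usage threshold on corrected OD (default 0.005).
#' @param seed Master seed; each randomized stage receives an independent
#'   child seed derived from it.
#' @param permutations Named list: `permanova` (999), `permdisp` (9999),
#'   `mantel` (999).
#' @param fdr BH false-discovery-rate level recorded in outputs (0.05).
#' @return `out_dir`, invisibly.
#' @export
run_all <- function(plates_path, metadata_path, layout_path = NULL,
                    out_dir, alignments = NULL, distances = NULL,
                    threshold = 0.005, seed = 1L,
                    permutations = list(permanova = 999, permdisp = 9999,
                                        mantel = 999),
                    fdr = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(permanova = seed + 101L, permdisp = seed + 202L,
                mantel = seed + 303L)
  log_path <- file.path(out_dir, "run.log")
  logln <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
                             file = log_path, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste("stage", name, "failed:", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logln("stage", name, "done in", round(proc.time()[3] - t0, 2), "s")
    res
  }
  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
  }

  layout <- stage("ingest", {
    lay <- if (is.null(layout_path)) default_layout() else read_layout(layout_path)
    lay
  })
  plates <- stage("ingest", read_plates(plates_path, layout, metadata_path))
  profiles <- stage("correct", correct_and_threshold(plates, threshold))
  write_profiles(profiles, file.path(out_dir, "profiles.tsv"))

  metrics <- stage("metrics", metrics_table(profiles))
  write_metrics(metrics, file.path(out_dir, "metrics.tsv"))

  ov <- stage("overlap", overlap_table(profiles))
  wt(ov, "overlap.tsv")
  wt(group_overlap_summary(ov), "overlap_summary.tsv")

  tests <- stage("group_tests", {
    grp <- function(df, col, k, tr) df[[col]][df$kingdom == k & df$treatment == tr]
    ovg <- function(cls, tr) ov$omega_bar[ov$pair_class == cls & ov$treatment == tr]
    fam <- list(
      "evenness_B_control_vs_NPKu" = list(grp(metrics, "J", "Bacteria", "control"),
                                          grp(metrics, "J", "Bacteria", "NPKu")),
      "evenness_F_control_vs_NPKu" = list(grp(metrics, "J", "Fungi", "control"),
                                          grp(metrics, "J", "Fungi", "NPKu")),
      "overlap_BF_control_vs_NPKu" = list(ovg("B:F", "control"), ovg("B:F", "NPKu")),
      "overlap_FB_control_vs_NPKu" = list(ovg("F:B", "control"), ovg("F:B", "NPKu")),
      "overlap_BB_control_vs_NPKu" = list(ovg("B:B", "control"), ovg("B:B", "NPKu")),
      "overlap_FF_control_vs_NPKu" = list(ovg("F:F", "control"), ovg("F:F", "NPKu")))
    comparison_family(fam)
  })
  wt(tests, "group_tests.tsv")

  d_bc <- stage("bray_curtis", bray_curtis(profiles))
  write_phylip_square(d_bc, file.path(out_dir, "bray_curtis.phylip"))

  perm <- stage("permanova", permanova_terms(
    d_bc, profiles$meta, ~ kingdom * treatment,
    permutations = permutations$permanova, seed = seeds$permanova))
  wt(perm, "permanova.tsv")

  disp <- stage("permdisp", {
    grpfac <- interaction(profiles$meta$kingdom, profiles$meta$treatment)
    dispersion_test(d_bc, grpfac, permutations = permutations$permdisp,
                    seed = seeds$permdisp)
  })
  wt(data.frame(group = names(disp$group_means),
                mean_dist_to_center = as.vector(disp$group_means),
                F = disp$F, p_value = disp$p_value), "permdisp.tsv")
  wt(disp$tukey, "permdisp_tukey.tsv")

  models <- stage("metric_models", {
    rows <- lapply(c("NW", "TG", "GE"), function(r) {
      mm <- suppressWarnings(metric_model(metrics, r))
      data.frame(response = r, contrast = mm$contrasts$contrast,
                 estimate = mm$contrasts$estimate, SE = mm$contrasts$SE,
                 p_value = mm$contrasts$p.value, family = mm$family,
                 warnings = paste(mm$warnings, collapse = "; "),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  wt(models, "metric_model_contrasts.tsv")

  # phylogeny stages: optional inputs
  d_phylo <- NULL
  if (!is.null(distances)) {
    d_phylo <- stage("phylo", lapply(distances, read_phylip_square))
  } else if (!is.null(alignments)) {
    d_phylo <- stage("phylo", lapply(alignments, function(p) {
      distance_matrix(read_alignment(p), model = "p")
    }))
  } else {
    logln("phylo stages skipped: no alignments or distance matrices supplied")
    warning("phylo stages skipped: no alignments or distance matrices supplied")
  }
  if (!is.null(d_phylo)) {
    mant <- stage("mantel", {
      rows <- lapply(names(d_phylo), function(k) {
        ids <- intersect(profiles$meta$isolate_id[profiles$meta$kingdom == k],
                         attr(d_phylo[[k]], "Labels"))
        dp <- stats::as.dist(as.matrix(d_bc)[ids, ids])
        dg <- stats::as.dist(as.matrix(d_phylo[[k]])[ids, ids])
        cbind(kingdom = k, mantel_test(dp, dg,
                                       permutations = permutations$mantel,
                                       seed = seeds$mantel))
      })
      do.call(rbind, rows)
    })
    wt(mant, "mantel.tsv")
    reg <- stage("phylo_regression", {
      rows <- lapply(names(d_phylo), function(k) {
        sub <- profiles$meta[profiles$meta$kingdom == k, ]
        ids <- intersect(sub$isolate_id, attr(d_phylo[[k]], "Labels"))
        strata <- stats::setNames(paste(k, sub$treatment[match(ids, sub$isolate_id)]),
                                  ids)
        phylo_pheno_regression(as.matrix(d_bc)[ids, ids],
                               as.matrix(d_phylo[[k]])[ids, ids], strata)
      })
      do.call(rbind, rows)
    })
    wt(reg, "phylo_regression.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("endoniche")),
    threshold = threshold, seed = seed, child_seeds = seeds,
    permutations = permutations, fdr = fdr,
    inputs = list(plates = plates_path, metadata = metadata_path,
                  layout = if (is.null(layout_path)) "shipped-default" else layout_path),
    n_isolates = nrow(profiles$od))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Directions of the planted treatment effects in one simulated study
#'
#' Runs the treatment comparisons the study reports: niche width and total
#' growth via the kingdom x treatment mixed model (leaf random intercept)
#' with least-squares-means contrasts, evenness and niche overlap via the
#' normality-routed two-sample test. Reports, per effect, the direction of
#' the control-minus-NPKu difference and its p value. Used for calibration
#' and direction-recovery checks.
#'
#' @param profiles An `isolate_profiles` object.
#' @return data.frame: `effect`, `mean_control`, `mean_npku`, `direction`
#'   (sign of control minus NPKu), `p_value`, `test_used`.
#' @export
effect_direction_report <- function(profiles) {
  metrics <- metrics_table(profiles)
  ov <- overlap_table(profiles)
  pick <- function(df, col, k, tr) df[[col]][df$kingdom == k & df$treatment == tr]
  ovg <- function(cls, tr) ov$omega_bar[ov$pair_class == cls & ov$treatment == tr]
  mm <- list(NW = metric_model(metrics, "NW"), TG = metric_model(metrics, "TG"))
  rows <- list()
  for (resp in c("NW", "TG")) {
    for (k in KINGDOMS) {
      ctr <- treatment_contrast(mm[[resp]], k)
      a <- pick(metrics, resp, k, "control"); b <- pick(metrics, resp, k, "NPKu")
      rows[[length(rows) + 1L]] <- data.frame(
        effect = paste0(c(Bacteria = "bacterial", Fungi = "fungal")[k], "_", resp),
        mean_control = mean(a), mean_npku = mean(b),
        direction = sign(ctr$estimate), p_value = ctr$p_value,
        test_used = paste0("mixed_model_", mm[[resp]]$family),
        stringsAsFactors = FALSE)
    }
  }
  specs <- list(
    fungal_evenness = list(pick(metrics, "J", "Fungi", "control"),
                           pick(metrics, "J", "Fungi", "NPKu")),
    bacterial_evenness = list(pick(metrics, "J", "Bacteria", "control"),
                              pick(metrics, "J", "Bacteria", "NPKu")),
    overlap_BF = list(ovg("B:F", "control"), ovg("B:F", "NPKu")),
    overlap_FB = list(ovg("F:B", "control"), ovg("F:B", "NPKu")),
    overlap_BB = list(ovg("B:B", "control"), ovg("B:B", "NPKu")),
    overlap_FF = list(ovg("F:F", "control"), ovg("F:F", "NPKu")))
  for (nm in names(specs)) {
    a <- specs[[nm]][[1]]; b <- specs[[nm]][[2]]
    ts <- two_sample_auto(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = nm, mean_control = mean(a, na.rm = TRUE),
      mean_npku = mean(b, na.rm = TRUE),
      direction = sign(mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)),
      p_value = ts$p_value, test_used = ts$test_used,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
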