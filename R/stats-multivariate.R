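#' Bray-Curtis dissimilarity of carbon-use profiles
#'
#' Computed on the clipped corrected OD matrix over all substrates,
#' BC(x, y) = sum|x_n - y_n| / sum(x_n + y_n). A pair in which both isolates
#' have an all-zero profile has no defined dissimilarity; such entries are
#' set to 1 and flagged via the `"allzero_pairs"` attribute.
#'
#' @param profiles An `isolate_profiles` object, or a nonnegative numeric
#'   matrix (samples x variables).
#' @param raw Use unclipped corrected ODs (sensitivity flag; negative values
#'   rejected by vegan). Default FALSE.
#' @return A `dist` object with isolate labels.
#' @export
bray_curtis <- function(profiles, raw = FALSE) {
  if (inherits(profiles, "isolate_profiles")) {
    m <- if (raw) profiles$od else profiles$od_clipped
    rownames(m) <- profiles$meta$isolate_id
  } else {
    m <- as.matrix(profiles)
  }
  if (nrow(m) < 2) stop("need at least 2 profiles")
  d <- vegan::vegdist(m, method = "bray")
  nz <- sum(is.na(d))
  if (nz > 0) {
    d[is.na(d)] <- 1
    attr(d, "allzero_pairs") <- nz
  }
  d
}

as_dist_checked <- function(d, labels = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
    if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
    d <- stats::as.dist(d)
  }
  d
}

#' PERMANOVA on a distance matrix
#'
#' Sequential (Type-I) sums of squares via `vegan::adonis2`, default model
#' `~ kingdom * treatment`, free permutation of rows. `permutations` may be
#' an integer count or an explicit permutation matrix (one permutation per
#' row), which makes exhaustive-enumeration testing possible.
#'
#' @param d `dist` or symmetric matrix.
#' @param meta data.frame of sample factors, rows aligned with `d` labels.
#' @param formula RHS-only model formula (default `~ kingdom * treatment`).
#' @param permutations Count (default 999) or permutation matrix.
#' @param seed Optional integer seed for reproducible permutations.
#' @return data.frame: `term`, `df`, `SumOfSqs`, `R2`, `F`, `p_value`.
#' @export
permanova_terms <- function(d, meta, formula = ~ kingdom * treatment,
                            permutations = 999, seed = NULL) {
  d <- as_dist_checked(d)
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(meta))
  if (length(miss)) stop("factors not in meta: ", paste(miss, collapse = ", "))
  for (v in vars) {
    tb <- table(meta[[v]])
    if (any(tb < 2)) stop("factor ", v, " has a level with < 2 samples")
  }
  if (!is.null(seed)) set.seed(seed)
  f <- stats::as.formula(paste("d ~", as.character(formula)[2]))
  res <- vegan::adonis2(f, data = meta, permutations = permutations,
                        by = "terms")
  out <- data.frame(term = rownames(res), df = res$Df,
                    SumOfSqs = res$SumOfSqs, R2 = res$R2, F = res$F,
                    p_value = res$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' `vegan::betadisper` on a principal-coordinates embedding of the distance
#' matrix (default center: spatial median), followed by a permutation F test
#' on the distances to center and Tukey's HSD on group means.
#'
#' @param d `dist` or symmetric matrix.
#' @param groups Factor of group membership, aligned with `d`.
#' @param permutations Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @param center `"median"` (spatial median, default) or `"centroid"`.
#' @return List: `group_means` (mean distance to center per group), `F`,
#'   `p_value`, `tukey` (data.frame of pairwise contrasts), `model`
#'   (the betadisper fit), `distances`.
#' @export
dispersion_test <- function(d, groups, permutations = 9999, seed = NULL,
                            center = c("median", "centroid")) {
  d <- as_dist_checked(d)
  center <- match.arg(center)
  groups <- as.factor(groups)
  fit <- vegan::betadisper(d, groups, type = center)
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::permutest(fit, permutations = permutations)
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk), as.data.frame(tk),
                      row.names = NULL, check.names = FALSE)
  list(group_means = tapply(fit$distances, fit$group, mean),
       F = pt$tab$F[1],
       p_value = pt$tab$`Pr(>F)`[1],
       tukey = tukey,
       model = fit,
       distances = fit$distances)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of corresponding off-diagonal entries; one-sided
#' permutation p by simultaneous row/column permutation of the second
#' matrix, p = (b + 1) / (B + 1).
#'
#' @param d1,d2 `dist` objects or symmetric matrices with matching labels.
#' @param permutations Count (default 999) or permutation matrix.
#' @param seed Optional integer seed.
#' @return data.frame row: `r`, `p_value`, `n`, `permutations`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = NULL) {
  d1 <- as_dist_checked(d1); d2 <- as_dist_checked(d2)
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2)) {
    if (!identical(l1, l2)) {
      if (!setequal(l1, l2)) stop("distance matrices have different labels")
      m2 <- as.matrix(d2)[l1, l1]
      d2 <- stats::as.dist(m2)
    }
  }
  if (attr(d1, "Size") != attr(d2, "Size")) stop("distance matrices differ in size")
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::mantel(d1, d2, method = "pearson", permutations = permutations)
  data.frame(r = unname(res$statistic), p_value = res$signif,
             n = attr(d1, "Size"),
             permutations = if (is.matrix(permutations)) nrow(permutations) else permutations)
}

#' Regress phenotype dissimilarity on phylogenetic distance, per stratum
#'
#' Ordinary least squares of pairwise carbon-use dissimilarity on pairwise
#' phylogenetic distance, within each stratum (e.g. kingdom x treatment
#' cell); pairs span isolates of the same stratum only. Pairwise
#' observations are not independent, so the nominal p value is reported with
#' a caveat flag.
#'
#' @param d_pheno,d_phylo `dist` objects or symmetric matrices sharing
#'   labels (d_phylo may cover a subset).
#' @param strata Named factor/character: stratum of each isolate, named by
#'   label. A single-level vector collapses to one overall regression.
#' @return data.frame: one row per stratum with `slope`, `intercept`, `R2`,
#'   `p_value`, `n_pairs`; attribute `"nonindependent_pairs" = TRUE`.
#' @export
phylo_pheno_regression <- function(d_pheno, d_phylo, strata) {
  mp <- as.matrix(as_dist_checked(d_pheno))
  mg <- as.matrix(as_dist_checked(d_phylo))
  common <- intersect(rownames(mp), rownames(mg))
  if (length(common) < 3) stop("need at least 3 shared labels")
  res <- lapply(split(common, strata[common]), function(ids) {
    if (length(ids) < 3) return(NULL)
    sp <- mp[ids, ids]; sg <- mg[ids, ids]
    y <- sp[upper.tri(sp)]; x <- sg[upper.tri(sg)]
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    data.frame(slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               R2 = sm$r.squared,
               p_value = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                   sm$fstatistic[3], lower.tail = FALSE),
               n_pairs = length(y))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  out <- data.frame(stratum = names(res), do.call(rbind, res),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "nonindependent_pairs") <- TRUE
  out
}
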