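#' Directional pairwise niche overlap
#'
#' The overlap of isolate i onto isolate j's resource niche: for every
#' substrate on which both isolates meet the usage criterion, the ratio
#' OD_i / OD_j capped at 1 (the fraction of j's growth matched by i); all
#' other substrates contribute 0; the 95 per-substrate terms are averaged
#' with a fixed denominator of 95. The statistic is directional --
#' omega(i -> j) and omega(j -> i) generally differ -- and lies in [0, 1].
#'
#' @param od_i,od_j Clipped corrected OD vectors (same layout order).
#' @param used_i,used_j Logical usage vectors.
#' @param denominator Averaging denominator: `"plate"` (the full substrate
#'   count, default and the definition used throughout) or `"shared"`
#'   (number of co-used substrates, for sensitivity analysis; 0 shared
#'   substrates gives 0).
#' @return Mean overlap, a scalar in [0, 1].
#' @export
pairwise_overlap <- function(od_i, od_j, used_i, used_j,
                             denominator = c("plate", "shared")) {
  denominator <- match.arg(denominator)
  stopifnot(length(od_i) == length(od_j),
            length(used_i) == length(od_i),
            length(used_j) == length(od_j))
  both <- used_i & used_j
  num <- sum(pmin(od_i[both] / od_j[both], 1))
  den <- if (denominator == "plate") length(od_i) else sum(both)
  if (den == 0L) return(0)
  num / den
}

#' Enumerate sympatric ordered pairs
#'
#' All ordered pairs of distinct isolates sharing a leaf: a leaf carrying m
#' isolates contributes m(m-1) ordered pairs. Each pair is classed by
#' source:target kingdom (B:B, F:F, B:F, F:B).
#'
#' @param meta Metadata data.frame (`isolate_id`, `kingdom`, `treatment`,
#'   `leaf_id`).
#' @return An object of class `pair_universe`: list with `pairs` (data.frame
#'   `source_id,target_id,leaf_id,treatment,pair_class`) and `counts` (table
#'   of pair_class x treatment).
#' @export
sympatric_pairs <- function(meta) {
  if (anyNA(meta$leaf_id)) stop("leaf_id required for every isolate")
  out <- lapply(split(meta, meta$leaf_id), function(m) {
    n <- nrow(m)
    if (n < 2L) return(NULL)
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$i != idx$j, ]
    data.frame(
      source_id = m$isolate_id[idx$i],
      target_id = m$isolate_id[idx$j],
      leaf_id = m$leaf_id[1],
      treatment = m$treatment[idx$i],
      pair_class = paste0(substr(m$kingdom[idx$i], 1, 1), ":",
                          substr(m$kingdom[idx$j], 1, 1)),
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) {
    pairs <- data.frame(source_id = character(), target_id = character(),
                        leaf_id = character(), treatment = character(),
                        pair_class = character(), stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$leaf_id, pairs$source_id, pairs$target_id), ]
  rownames(pairs) <- NULL
  counts <- table(pair_class = factor(pairs$pair_class,
                                      c("B:B", "F:F", "B:F", "F:B")),
                  treatment = factor(pairs$treatment, TREATMENTS))
  structure(list(pairs = pairs, counts = counts), class = "pair_universe")
}

#' @export
print.pair_universe <- function(x, ...) {
  cat("pair_universe:", nrow(x$pairs), "ordered sympatric pairs\n")
  print(x$counts)
  invisible(x)
}

#' Overlap table over all sympatric ordered pairs
#'
#' Applies [pairwise_overlap()] to every ordered within-leaf pair,
#' deterministically ordered by (leaf, source, target). Cross-leaf pairs can
#' be included for exploration but are excluded from every reported summary.
#'
#' @param profiles An `isolate_profiles` object.
#' @param sympatric_only Restrict to within-leaf pairs (default TRUE).
#' @param denominator Passed to [pairwise_overlap()].
#' @return data.frame `source_id,target_id,leaf_id,treatment,pair_class,
#'   omega_bar`.
#' @export
overlap_table <- function(profiles, sympatric_only = TRUE,
                          denominator = c("plate", "shared")) {
  stopifnot(inherits(profiles, "isolate_profiles"))
  denominator <- match.arg(denominator)
  meta <- profiles$meta
  if (!sympatric_only) {
    meta <- transform(meta, leaf_id = "all")
  }
  pu <- sympatric_pairs(meta)
  pairs <- pu$pairs
  if (sympatric_only == FALSE) pairs$leaf_id <- NA_character_
  od <- profiles$od_clipped
  use <- profiles$usage
  si <- match(pairs$source_id, profiles$meta$isolate_id)
  ti <- match(pairs$target_id, profiles$meta$isolate_id)
  nsub <- ncol(od)
  omega <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- si[k]; j <- ti[k]
    both <- use[i, ] & use[j, ]
    num <- sum(pmin(od[i, both] / od[j, both], 1))
    den <- if (denominator == "plate") nsub else sum(both)
    if (den == 0L) 0 else num / den
  }, numeric(1))
  pairs$omega_bar <- omega
  pairs
}

#' Summarize overlap by pair class and treatment
#'
#' @param entries data.frame from [overlap_table()].
#' @return data.frame with one row per (pair_class, treatment) cell:
#'   `n`, `mean`, `sd` of omega_bar (`mean`/`sd` NA for empty cells).
#' @export
group_overlap_summary <- function(entries) {
  cells <- expand.grid(pair_class = c("B:B", "F:F", "B:F", "F:B"),
                       treatment = TREATMENTS, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    v <- entries$omega_bar[entries$pair_class == cells$pair_class[k] &
                             entries$treatment == cells$treatment[k]]
    data.frame(cells[k, ], n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
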