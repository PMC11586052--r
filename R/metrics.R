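#' Niche width
#'
#' Number of substrates an isolate uses (corrected OD at or above the usage
#' threshold).
#'
#' @param profiles An `isolate_profiles` object.
#' @return Named integer vector, one entry per isolate.
#' @export
niche_width <- function(profiles) {
  stopifnot(inherits(profiles, "isolate_profiles"))
  stats::setNames(as.integer(rowSums(profiles$usage)), profiles$meta$isolate_id)
}

#' Total growth
#'
#' Sum of corrected OD over used substrates only; positive but sub-threshold
#' wells contribute nothing.
#'
#' @inheritParams niche_width
#' @return Named numeric vector (OD590 units).
#' @export
total_growth <- function(profiles) {
  stopifnot(inherits(profiles, "isolate_profiles"))
  stats::setNames(rowSums(profiles$od * profiles$usage), profiles$meta$isolate_id)
}

#' Growth efficiency
#'
#' Mean corrected OD per used substrate, TG/NW. `NA` when the isolate uses no
#' substrate (never a division error).
#'
#' @inheritParams niche_width
#' @return Named numeric vector.
#' @export
growth_efficiency <- function(profiles) {
  nw <- niche_width(profiles)
  tg <- total_growth(profiles)
  ifelse(nw >= 1L, tg / nw, NA_real_)
}

#' Pielou evenness of carbon use
#'
#' Shannon entropy of the isolate's used-substrate OD proportions normalized
#' by its maximum: J = H' / ln(NW) with p_n = OD_n / TG over used substrates.
#' High J means a generalist pattern (similar growth on every used
#' substrate). `NA` when fewer than two substrates are used.
#'
#' @inheritParams niche_width
#' @return Named numeric vector in [0, 1] (NA where undefined).
#' @export
evenness <- function(profiles) {
  stopifnot(inherits(profiles, "isolate_profiles"))
  res <- apply_rows(profiles, function(od, used) {
    s <- sum(used)
    if (s < 2L) return(NA_real_)
    p <- od[used] / sum(od[used])
    -sum(p * log(p)) / log(s)
  })
  stats::setNames(res, profiles$meta$isolate_id)
}

apply_rows <- function(profiles, f) {
  vapply(seq_len(nrow(profiles$od)), function(i) {
    f(profiles$od[i, ], profiles$usage[i, ])
  }, numeric(1))
}

#' Per-isolate carbon-use metrics table
#'
#' @inheritParams niche_width
#' @return data.frame with metadata plus `NW`, `TG`, `GE`, `J`, one row per
#'   isolate in metadata order. Undefined metrics are `NA`.
#' @export
metrics_table <- function(profiles) {
  data.frame(profiles$meta,
             NW = unname(niche_width(profiles)),
             TG = unname(total_growth(profiles)),
             GE = unname(growth_efficiency(profiles)),
             J = unname(evenness(profiles)),
             stringsAsFactors = FALSE)
}

#' Write a metrics table; undefined values are empty fields, never 0
#'
#' @param metrics data.frame from [metrics_table()].
#' @param path Output path (tab-delimited).
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Preferred substrates of a group of isolates
#'
#' Substrates ranked by mean clipped corrected OD across the selected
#' isolates (all isolates contribute on every substrate, used or not);
#' the top `k` are returned. Ties are broken by substrate name, ascending.
#'
#' @param profiles An `isolate_profiles` object.
#' @param select Logical/integer/character isolate selector (default: all).
#' @param k Number of substrates to return (default 10).
#' @return Character vector of `k` substrate names, best first.
#' @export
preferred_substrates <- function(profiles, select = NULL, k = 10) {
  stopifnot(inherits(profiles, "isolate_profiles"))
  if (!is.null(select)) profiles <- subset_profiles(profiles, select)
  if (nrow(profiles$od) == 0L) stop("empty selection")
  mu <- colMeans(profiles$od_clipped)
  ord <- order(-mu, names(mu))
  names(mu)[ord][seq_len(min(k, length(mu)))]
}
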