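# Fixture builders and independent brute-force oracles.

# a 95-vector with named positions set, rest a default value
od_vec <- function(..., fill = 0) {
  v <- rep(fill, 95)
  args <- c(...)
  if (length(args)) v[seq_along(args)] <- args
  v
}

# minimal metadata for n isolates on leaves
fix_meta <- function(n, kingdom = "Bacteria", treatment = "control",
                     leaf = "leaf1") {
  data.frame(isolate_id = sprintf("iso%02d", seq_len(n)),
             kingdom = rep_len(kingdom, n), treatment = rep_len(treatment, n),
             leaf_id = rep_len(leaf, n), plot_id = "p1",
             stringsAsFactors = FALSE)
}

# write a layout file with a given number of rows / water flags
write_layout_file <- function(path, n_rows = 96, n_water = 1) {
  ids <- well_ids()[seq_len(n_rows)]
  tab <- data.frame(well = ids,
                    substrate = c(rep("water", n_water),
                                  sprintf("C%03d", seq_len(n_rows - n_water) + 1)),
                    is_water = rep(c(1, 0), c(n_water, n_rows - n_water)))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# raw_plates object built in memory (bypassing files)
raw_plates_from <- function(mat, meta, layout = default_layout()) {
  rownames(mat) <- meta$isolate_id
  colnames(mat) <- layout$wells
  structure(list(absorbance = mat, meta = meta, layout = layout),
            class = "raw_plates")
}

# ---- independent oracles ----

# naive per-substrate loop for the directional overlap statistic
bf_overlap <- function(od_i, od_j, used_i, used_j) {
  total <- 0
  for (n in seq_along(od_i)) {
    if (used_i[n] && used_j[n]) {
      r <- od_i[n] / od_j[n]
      if (r > 1) r <- 1
      total <- total + r
    }
  }
  as.numeric(total) / length(od_i)
}

bf_bray_curtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

# all permutations of 1..n (n! rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# pseudo-F from Gower-centered distance matrix, one grouping factor
bf_pseudo_f <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  a <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% a %*% J
  sst <- sum(diag(G))
  X <- model.matrix(~groups)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ssb <- sum(diag(H %*% G %*% H))
  ssw <- sst - ssb
  dfb <- length(unique(groups)) - 1
  dfw <- n - length(unique(groups))
  (ssb / dfb) / (ssw / dfw)
}

# exact one-factor PERMANOVA p by exhaustive enumeration (identity included)
bf_permanova_p <- function(d, groups) {
  n <- attr(d, "Size")
  f0 <- bf_pseudo_f(d, groups)
  perms <- all_perms(n)
  fs <- apply(perms, 1, function(p) bf_pseudo_f(d, groups[p]))
  mean(fs >= f0 - 1e-12)
}

mantel_r <- function(d1, d2) cor(as.vector(d1), as.vector(d2))

# exact one-sided Mantel p by exhaustive enumeration (identity included)
bf_mantel_p <- function(d1, d2) {
  n <- attr(d1, "Size")
  m2 <- as.matrix(d2)
  r0 <- mantel_r(d1, d2)
  perms <- all_perms(n)
  rs <- apply(perms, 1, function(p) mantel_r(d1, as.dist(m2[p, p])))
  mean(rs >= r0 - 1e-12)
}

# p-distance by direct site counting (pairwise-complete sites)
bf_p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok]) / sum(ok)
}

write_fasta <- function(path, seqs) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}
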