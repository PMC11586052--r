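#' Read a multiple sequence alignment (FASTA)
#'
#' @param path FASTA file of aligned sequences.
#' @return A `DNAbin` matrix (labels x sites). Errors on ragged lengths or
#'   duplicate labels.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  if (lens[1] < 1) stop("zero-length alignment")
  as.matrix(seqs)
}

#' Pairwise phylogenetic distance matrix from an alignment
#'
#' Uncorrected p-distance (proportion of differing sites among
#' pairwise-complete sites: positions where neither sequence has a gap or
#' ambiguity are compared, the rest dropped per pair), or its Jukes-Cantor
#' correction d = -(3/4) ln(1 - (4/3) p), undefined (NA) at p >= 0.75.
#' Bacterial 16S and fungal ITS alignments are processed separately, never
#' mixed; call once per kingdom.
#'
#' @param aln A `DNAbin` matrix from [read_alignment()].
#' @param model `"p"` (default) or `"jc69"`.
#' @return A `dist` object labelled by sequence name, in alignment order.
#' @export
distance_matrix <- function(aln, model = c("p", "jc69")) {
  model <- match.arg(model)
  p <- ape::dist.dna(aln, model = "raw", pairwise.deletion = TRUE)
  if (model == "p") return(p)
  jc69_from_p(p)
}

#' Jukes-Cantor correction of a p-distance
#'
#' @param p Proportion(s) of differing sites, or a `dist` of them.
#' @return Corrected distance(s); NA (with a warning) where p >= 0.75.
#' @export
jc69_from_p <- function(p) {
  bad <- !is.na(p) & p >= 0.75
  if (any(bad)) warning(sum(bad), " pairwise p-distance(s) >= 0.75; JC69 undefined")
  out <- p
  out[] <- ifelse(bad, NA_real_, -0.75 * log(1 - (4 / 3) * unclass(p)))
  out
}

#' Read / write labelled square distance matrices (PHYLIP square format)
#'
#' Relaxed PHYLIP: first line the number of taxa, then one row per taxon,
#' whitespace-separated, labels unpadded.
#'
#' @param path File path.
#' @return [read_phylip_square()]: a `dist` object.
#' @export
read_phylip_square <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1) stop("malformed PHYLIP matrix")
  rows <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1)
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(m) <- list(labels, labels)
  if (!isTRUE(all.equal(m, t(m)))) stop("matrix not symmetric")
  stats::as.dist(m)
}

#' @param d A `dist` object or symmetric matrix.
#' @rdname read_phylip_square
#' @export
write_phylip_square <- function(d, path) {
  m <- as.matrix(d)
  lines <- c(as.character(nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
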