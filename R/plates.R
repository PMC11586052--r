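#' @title Plate tables and isolate profiles
#' @name plates
#' @description
#' Raw plates hold one 96-well OD590 absorbance record per isolate together
#' with isolate metadata (kingdom, treatment, leaf, plot). Water correction
#' subtracts the water-control well from every substrate well; an isolate is
#' scored as using a substrate when the corrected OD meets the usage
#' threshold (default 0.005, inclusive).
NULL

KINGDOMS <- c("Bacteria", "Fungi")

# Usage criterion: corrected OD >= threshold, inclusive. The tiny tolerance
# keeps the boundary inclusive under floating-point subtraction
# (e.g. 0.055 - 0.050 < 0.005 in doubles by ~3e-18).
usage_mask <- function(od, threshold) od - threshold >= -1e-9
TREATMENTS <- c("control", "NPKu")

# Canonicalize treatment labels: the micro sign variant of the amended
# treatment is accepted on input and stored as ASCII "NPKu".
canon_treatment <- function(x) {
  x <- as.character(x)
  x[x %in% c("NPK\u03bc", "NPK\u00b5")] <- "NPKu"
  x
}

validate_metadata <- function(meta) {
  need <- c("isolate_id", "kingdom", "treatment", "leaf_id", "plot_id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  meta$isolate_id <- as.character(meta$isolate_id)
  meta$treatment <- canon_treatment(meta$treatment)
  if (anyDuplicated(meta$isolate_id)) {
    stop("duplicate isolate_id in metadata: ",
         paste(unique(meta$isolate_id[duplicated(meta$isolate_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(meta$kingdom), KINGDOMS)
  if (length(bad)) {
    stop("unknown kingdom for isolates ",
         paste(meta$isolate_id[meta$kingdom %in% bad], collapse = ", "),
         ": ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(meta$treatment), TREATMENTS)
  if (length(bad)) {
    stop("unknown treatment for isolates ",
         paste(meta$isolate_id[meta$treatment %in% bad], collapse = ", "),
         ": ", paste(bad, collapse = ", "))
  }
  meta$leaf_id <- as.character(meta$leaf_id)
  meta$plot_id <- as.character(meta$plot_id)
  meta[, need]
}

#' Read raw plate tables with isolate metadata
#'
#' Accepts the wide dialect (one row per isolate: `isolate_id,A1,...,H12`) or
#' the long dialect (columns `isolate_id,well,absorbance`). Isolates in the
#' plate table but absent from the metadata are rejected; isolate order
#' follows the metadata table.
#'
#' @param path Plate table (comma- or tab-delimited).
#' @param layout A `plate_layout`.
#' @param metadata_path Metadata table with columns
#'   `isolate_id,kingdom,treatment,leaf_id,plot_id`.
#' @return An object of class `raw_plates`: list with `absorbance` (numeric
#'   matrix, isolates x 96 wells in canonical order), `meta` (data.frame),
#'   and `layout`.
#' @export
read_plates <- function(path, layout, metadata_path) {
  stopifnot(inherits(layout, "plate_layout"))
  meta <- validate_metadata(read_delim_sniff(metadata_path))
  tab <- read_delim_sniff(path)
  ids <- layout$wells
  if (all(c("isolate_id", "well") %in% names(tab))) {
    # long dialect
    vcol <- intersect(c("absorbance", "od", "value"), names(tab))[1]
    if (is.na(vcol)) stop("long plate table needs an absorbance column")
    tab$well <- toupper(trimws(as.character(tab$well)))
    wide <- matrix(NA_real_, nrow = length(unique(tab$isolate_id)), ncol = 96,
                   dimnames = list(unique(as.character(tab$isolate_id)), ids))
    idx <- cbind(match(as.character(tab$isolate_id), rownames(wide)),
                 match(tab$well, ids))
    if (anyNA(idx[, 2])) stop("unknown well labels in plate table")
    wide[idx] <- suppressWarnings(as.numeric(tab[[vcol]]))
    mat <- wide
  } else if ("isolate_id" %in% names(tab)) {
    have <- intersect(ids, names(tab))
    miss_cols <- setdiff(ids, names(tab))
    if (length(miss_cols)) {
      stop("plate table missing well columns: ", paste(miss_cols, collapse = ", "))
    }
    mat <- as.matrix(tab[, ids])
    mat <- apply(mat, 2, function(v) suppressWarnings(as.numeric(v)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, ids))
    rownames(mat) <- as.character(tab$isolate_id)
    stopifnot(length(have) == 96L)
  } else {
    stop("plate table must contain an isolate_id column")
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate isolate_id in plate table: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  no_meta <- setdiff(rownames(mat), meta$isolate_id)
  if (length(no_meta)) {
    stop("isolates lacking metadata: ", paste(no_meta, collapse = ", "))
  }
  no_plate <- setdiff(meta$isolate_id, rownames(mat))
  if (length(no_plate)) {
    stop("isolates in metadata without plates: ", paste(no_plate, collapse = ", "))
  }
  mat <- mat[meta$isolate_id, , drop = FALSE]
  for (i in seq_len(nrow(mat))) {
    if (anyNA(mat[i, ])) {
      bad <- ids[is.na(mat[i, ])]
      stop("isolate ", rownames(mat)[i],
           " missing wells or non-numeric absorbance: ", paste(bad, collapse = ", "))
    }
  }
  if (any(!is.finite(mat))) stop("non-finite absorbance values")
  structure(list(absorbance = mat, meta = meta, layout = layout),
            class = "raw_plates")
}

#' Water-correct and threshold raw plates
#'
#' Subtracts each plate's water-control absorbance from its 95 substrate
#' wells and scores substrate usage as corrected OD >= `threshold`
#' (inclusive). Negative corrected ODs are retained in `od` and clipped to 0
#' in `od_clipped` for use wherever a nonnegative abundance is required
#' (Bray-Curtis, overlap ratios, evenness).
#'
#' @param plates A `raw_plates` object.
#' @param threshold Usage threshold on corrected OD (default 0.005).
#' @return An object of class `isolate_profiles`: list with `od` (isolates x
#'   95 corrected ODs, columns named by substrate), `od_clipped`, `usage`
#'   (logical matrix), `meta`, `substrates`, `threshold`.
#' @export
correct_and_threshold <- function(plates, threshold = 0.005) {
  stopifnot(inherits(plates, "raw_plates"))
  layout <- plates$layout
  water <- plates$absorbance[, layout$water_well]
  sub_wells <- names(layout$substrates)
  od <- plates$absorbance[, sub_wells, drop = FALSE] - water
  colnames(od) <- unname(layout$substrates)
  usage <- usage_mask(od, threshold)
  structure(list(
    od = od,
    od_clipped = pmax(od, 0),
    usage = usage,
    meta = plates$meta,
    substrates = unname(layout$substrates),
    threshold = threshold
  ), class = "isolate_profiles")
}

#' @export
print.isolate_profiles <- function(x, ...) {
  cat("isolate_profiles:", nrow(x$od), "isolates x", ncol(x$od),
      "substrates (threshold", x$threshold, ")\n")
  invisible(x)
}

n_isolates <- function(profiles) nrow(profiles$od)

#' Subset isolate profiles
#'
#' @param profiles An `isolate_profiles` object.
#' @param keep Logical, integer, or character (isolate id) index.
#' @return An `isolate_profiles` containing the selected isolates.
#' @export
subset_profiles <- function(profiles, keep) {
  if (is.character(keep)) keep <- match(keep, profiles$meta$isolate_id)
  profiles$od <- profiles$od[keep, , drop = FALSE]
  profiles$od_clipped <- profiles$od_clipped[keep, , drop = FALSE]
  profiles$usage <- profiles$usage[keep, , drop = FALSE]
  profiles$meta <- profiles$meta[keep, , drop = FALSE]
  rownames(profiles$meta) <- NULL
  profiles
}

#' Build isolate profiles from a corrected OD matrix
#'
#' Constructor for analyses that start from an already water-corrected
#' matrix (isolates x substrates) rather than raw plate files.
#'
#' @param od Numeric matrix, isolates in rows, substrates in columns.
#' @param meta Optional metadata data.frame (defaults name isolates
#'   `iso1..isoN`, all Bacteria/control on one leaf).
#' @param threshold Usage threshold (default 0.005).
#' @return An `isolate_profiles` object.
#' @export
profiles_from_od <- function(od, meta = NULL, threshold = 0.005) {
  od <- as.matrix(od)
  if (is.null(colnames(od))) colnames(od) <- sprintf("C%03d", seq_len(ncol(od)) + 1)
  if (is.null(meta)) {
    meta <- data.frame(isolate_id = sprintf("iso%d", seq_len(nrow(od))),
                       kingdom = "Bacteria", treatment = "control",
                       leaf_id = "leaf1", plot_id = "p1",
                       stringsAsFactors = FALSE)
  }
  meta <- validate_metadata(meta)
  stopifnot(nrow(meta) == nrow(od))
  rownames(od) <- meta$isolate_id
  structure(list(od = od, od_clipped = pmax(od, 0), usage = usage_mask(od, threshold),
                 meta = meta, substrates = colnames(od), threshold = threshold),
            class = "isolate_profiles")
}

#' Write corrected profiles to delimited text
#'
#' Wide table: metadata columns followed by one column per substrate holding
#' the corrected OD at full double precision, so a read/write round trip is
#' bit-exact on the corrected matrix.
#'
#' @param profiles An `isolate_profiles` object.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "isolate_profiles"))
  if (anyDuplicated(profiles$meta$isolate_id)) stop("duplicate isolate_id")
  odc <- apply(profiles$od, 2, function(v) sprintf("%.17g", v))
  if (is.null(dim(odc))) odc <- matrix(odc, nrow = 1)
  out <- cbind(profiles$meta, as.data.frame(odc))
  names(out) <- c(names(profiles$meta), colnames(profiles$od))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read corrected profiles written by [write_profiles()]
#'
#' @param path Path to a profiles table.
#' @param threshold Usage threshold to (re)apply.
#' @return An `isolate_profiles` object.
#' @export
read_profiles <- function(path, threshold = 0.005) {
  tab <- read_delim_sniff(path)
  meta_cols <- c("isolate_id", "kingdom", "treatment", "leaf_id", "plot_id")
  meta <- validate_metadata(tab[, meta_cols])
  subs <- setdiff(names(tab), meta_cols)
  od <- as.matrix(tab[, subs, drop = FALSE])
  storage.mode(od) <- "double"
  rownames(od) <- meta$isolate_id
  structure(list(
    od = od,
    od_clipped = pmax(od, 0),
    usage = usage_mask(od, threshold),
    meta = meta,
    substrates = subs,
    threshold = threshold
  ), class = "isolate_profiles")
}
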