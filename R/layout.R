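#' Canonical 96-well identifiers
#'
#' Well labels in row-major plate order: A1..A12, B1..B12, ..., H12.
#'
#' @return Character vector of length 96.
#' @export
well_ids <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Read a plate layout file
#'
#' A layout maps the 96 wells of an SF-P2 style plate to substrate names and
#' flags the single water-control well. Expected columns: `well`, `substrate`,
#' `is_water` (logical or 0/1). Comma- or tab-delimited (sniffed).
#'
#' @param path Path to the layout file.
#' @return An object of class `plate_layout`: a list with `wells` (the 96
#'   labels in canonical order), `substrates` (named character vector of the
#'   95 substrate names, named by well), and `water_well`.
#' @export
read_layout <- function(path) {
  tab <- read_delim_sniff(path)
  need <- c("well", "substrate", "is_water")
  if (!all(need %in% names(tab))) {
    stop("layout file must have columns: ", paste(need, collapse = ", "))
  }
  tab$well <- toupper(trimws(as.character(tab$well)))
  if (anyDuplicated(tab$well)) {
    stop("duplicate wells in layout: ",
         paste(unique(tab$well[duplicated(tab$well)]), collapse = ", "))
  }
  ids <- well_ids()
  if (nrow(tab) != 96L || !setequal(tab$well, ids)) {
    bad <- setdiff(tab$well, ids)
    if (length(bad)) {
      stop("unknown well labels in layout: ", paste(bad, collapse = ", "))
    }
    stop("expected 96 wells, found ", nrow(tab))
  }
  tab <- tab[match(ids, tab$well), ]
  isw <- as.logical(tab$is_water)
  if (anyNA(isw)) stop("is_water column must be logical or 0/1")
  if (sum(isw) > 1L) stop("multiple water wells: ",
                          paste(tab$well[isw], collapse = ", "))
  if (sum(isw) < 1L) stop("no water well flagged in layout")
  subs <- tab$substrate[!isw]
  if (anyDuplicated(subs)) {
    stop("duplicate substrate names: ",
         paste(unique(subs[duplicated(subs)]), collapse = ", "))
  }
  structure(list(
    wells = ids,
    substrates = stats::setNames(as.character(subs), tab$well[!isw]),
    water_well = tab$well[isw]
  ), class = "plate_layout")
}

#' Default SF-P2 plate layout
#'
#' The layout shipped with the package: water control at A1 and generic
#' substrate names (`C002`..`C096`, keyed to well position). Substrate
#' identity never enters any statistic, so placeholder names are sufficient;
#' a study-specific layout file can be supplied instead.
#'
#' @return A `plate_layout`.
#' @export
default_layout <- function() {
  path <- system.file("extdata", "sfp2_layout.tsv", package = "endoniche")
  if (!nzchar(path)) stop("shipped layout file not found")
  read_layout(path)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("plate_layout: 96 wells, 95 substrates, water at", x$water_well, "\n")
  invisible(x)
}

# Read a comma- or tab-delimited text table, sniffing the separator from the
# header line.
read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}
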