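#' Fluctuation-assay dataset
#'
#' Bundles the per-culture mutant colony counts of one fluctuation
#' experiment with the experiment-level metadata needed for rate
#' estimation: the final number of cells per culture (Nt, one OD-based
#' value for the whole experiment) and the fraction of each culture plated
#' on selective medium (epsilon), which thins the observed counts
#' binomially.
#'
#' @param counts non-negative integer vector, one observed mutant colony
#'   count per independent culture.
#' @param cells_per_culture positive scalar Nt, final cells per culture.
#' @param plating_fraction scalar in (0, 1]; fraction of each culture
#'   plated on selective medium. Default 1 (whole culture plated).
#' @param label free-text strain/condition label.
#' @return an object of class `fluctuation_data`.
#' @examples
#' fluctuation_data(c(0, 0, 1, 0, 7), cells_per_culture = 2^27)
#' @export
fluctuation_data <- function(counts, cells_per_culture,
                             plating_fraction = 1, label = "") {
  if (length(counts) < 1L) stop_input("at least one culture is required")
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop_input("counts must be non-negative integers")
  if (!is.numeric(cells_per_culture) || length(cells_per_culture) != 1L ||
      !is.finite(cells_per_culture) || cells_per_culture <= 0)
    stop_input("cells_per_culture must be a positive scalar")
  if (!is.numeric(plating_fraction) || length(plating_fraction) != 1L ||
      plating_fraction <= 0 || plating_fraction > 1)
    stop_input("plating_fraction must be in (0, 1]")
  if (cells_per_culture < max(counts) / plating_fraction)
    stop_input("cells_per_culture is smaller than max(counts)/plating_fraction")
  structure(
    list(counts = counts,
         cells_per_culture = cells_per_culture,
         plating_fraction = plating_fraction,
         label = as.character(label)[1L]),
    class = "fluctuation_data")
}

#' @export
print.fluctuation_data <- function(x, ...) {
  cat(sprintf(
    "<fluctuation_data> %s: %d cultures, Nt = %.4g, plating fraction = %g\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$counts), x$cells_per_culture, x$plating_fraction))
  cat(sprintf("  counts: %d zero, max %g, mean %.3g\n",
              sum(x$counts == 0), max(x$counts), mean(x$counts)))
  invisible(x)
}

#' Read a fluctuation-assay table from TSV
#'
#' The dialect is one row per culture with columns `culture_id` and
#' `mutant_count`, preceded by `#`-pragma header lines carrying the
#' dataset-level metadata, e.g. `# label = wild-type D`,
#' `# cells_per_culture = 134217728`, `# plating_fraction = 1`.
#'
#' @param path path to a TSV file.
#' @return a [fluctuation_data] object.
#' @export
read_fluctuation_tsv <- function(path) {
  lines <- readLines(path)
  prag <- grep("^#", lines, value = TRUE)
  meta <- list(label = "", cells_per_culture = NA_real_, plating_fraction = 1)
  for (p in prag) {
    kv <- sub("^#\\s*", "", p)
    m <- regmatches(kv, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", kv))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  if (is.na(suppressWarnings(as.numeric(meta$cells_per_culture))))
    stop_input("missing or malformed pragma: cells_per_culture")
  tab <- read.delim(textConnection(lines[!grepl("^#", lines)]),
                    sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("culture_id", "mutant_count") %in% names(tab)))
    stop_input("TSV must have columns culture_id and mutant_count")
  fluctuation_data(tab$mutant_count,
                   cells_per_culture = as.numeric(meta$cells_per_culture),
                   plating_fraction = as.numeric(meta$plating_fraction),
                   label = meta$label)
}

#' Write a fluctuation-assay table to TSV
#'
#' Inverse of [read_fluctuation_tsv()]: metadata as `#` pragmas, then one
#' row per culture.
#'
#' @param data a [fluctuation_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fluctuation_tsv <- function(data, path) {
  stopifnot(inherits(data, "fluctuation_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# label = %s", data$label),
    sprintf("# cells_per_culture = %.17g", data$cells_per_culture),
    sprintf("# plating_fraction = %.17g", data$plating_fraction),
    "culture_id\tmutant_count"), con)
  writeLines(sprintf("c%04d\t%.17g", seq_along(data$counts), data$counts), con)
  invisible(path)
}
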