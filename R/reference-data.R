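#' Published reference summary tables
#'
#' The raw respondent-level data of the nationwide survey the package
#' emulates are not public, but its published summary tables are, and they
#' are sufficient inputs for several whole-table computations: the
#' cross-tabulations of workload group against respondent characteristics
#' (for recomputing the chi-square statistics) and the binned distribution
#' of the comprehensive workload score (for reconstructing the distribution
#' table).
#'
#' `reference_crosstabs()` returns, per characteristic, the category-by-
#' group count matrix (groups low/medium/high/very high; N = 1,934).
#' `reference_distribution()` returns the score bins with their counts.
#'
#' @param characteristic optional single characteristic name; default
#'   returns all as a named list of matrices.
#' @return `reference_crosstabs()`: a count matrix, or a named list of
#'   them. `reference_distribution()`: data.frame with `lower`, `upper`,
#'   `n`.
#' @examples
#' chisq_pearson(reference_crosstabs("gender"))
#' @export
reference_crosstabs <- function(characteristic = NULL) {
  path <- system.file("extdata", "reference_crosstabs.csv",
                      package = "pcwload", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  split_df <- split(df, df$characteristic)
  tabs <- lapply(split_df, function(d) {
    m <- as.matrix(d[, pcw_group_labels(), drop = FALSE])
    rownames(m) <- d$category
    m
  })
  if (is.null(characteristic)) return(tabs)
  if (!characteristic %in% names(tabs))
    stop("no reference cross-tab for: ", characteristic)
  tabs[[characteristic]]
}

#' @rdname reference_crosstabs
#' @export
reference_distribution <- function() {
  path <- system.file("extdata", "reference_distribution.csv",
                      package = "pcwload", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
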