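#' Mental workload scale definition
#'
#' The hybrid NASA-TLX/SWAT physician mental workload instrument has six
#' dimensions -- mental demands (MD), physical demands (PD), temporal demands
#' (TD), perceived risk (PR), frustration level (FL) and performance (Pe) --
#' measured by 12 items rated on a 0--100 scale, plus 15 pairwise comparisons
#' of the six dimensions that yield per-respondent dimension weights.
#'
#' `mwl_scale()` builds the item-to-dimension mapping used by
#' [score_dimensions()]. The default assigns two items to each dimension
#' (`md1, md2, ..., pe2`); alternative mappings (for instance an unbalanced
#' item allocation from a revised instrument) can be supplied as long as all
#' 12 items are assigned and every dimension keeps at least one item.
#'
#' @param items named character vector mapping item identifier to dimension
#'   code; dimensions must be drawn from [mwl_dimensions()].
#' @return An object of class `mwl_scale`: a named character vector with the
#'   item mapping, validated.
#' @examples
#' sc <- mwl_scale()
#' table(sc)  # two items per dimension
#' @export
mwl_scale <- function(items = default_scale_items()) {
  if (is.null(names(items)) || anyNA(names(items)) || any(names(items) == ""))
    stop("scale items must be a named vector (item id -> dimension)")
  if (anyDuplicated(names(items)))
    stop("duplicated item identifiers in scale definition")
  if (length(items) != 12L)
    stop("the instrument has exactly 12 items; got ", length(items))
  bad <- setdiff(unique(items), mwl_dimensions())
  if (length(bad))
    stop("unknown dimension code(s): ", paste(bad, collapse = ", "))
  missing_dim <- setdiff(mwl_dimensions(), items)
  if (length(missing_dim))
    stop("dimension(s) with zero items: ", paste(missing_dim, collapse = ", "))
  structure(items, class = "mwl_scale")
}

#' @rdname mwl_scale
#' @export
mwl_dimensions <- function() c("MD", "PD", "TD", "PR", "FL", "Pe")

#' @rdname mwl_scale
#' @export
default_scale_items <- function() {
  dims <- mwl_dimensions()
  items <- rep(dims, each = 2L)
  names(items) <- paste0(tolower(rep(dims, each = 2L)), rep(1:2, 6L))
  items
}

#' All 15 unordered dimension pairs, in canonical order
#'
#' @return data.frame with columns `a`, `b` (dimension codes) and `pair`
#'   (the canonical pair id, e.g. `"md_pd"`), one row per C(6,2) pair.
#' @export
mwl_pairs <- function() {
  dims <- mwl_dimensions()
  idx <- utils::combn(6L, 2L)
  a <- dims[idx[1L, ]]
  b <- dims[idx[2L, ]]
  data.frame(a = a, b = b,
             pair = paste(tolower(a), tolower(b), sep = "_"),
             stringsAsFactors = FALSE)
}

#' Score the six scale dimensions from item ratings
#'
#' Each dimension score is the arithmetic mean of the ratings of its items.
#'
#' @param ratings either a named numeric vector of 12 item ratings, or a
#'   numeric matrix / data.frame with one row per respondent and one named
#'   column per item. Ratings must lie in \[0, 100\].
#' @param scale an [mwl_scale()] item mapping.
#' @return A numeric matrix (respondents x 6 dimensions, columns in
#'   [mwl_dimensions()] order), or a named length-6 vector when `ratings`
#'   was a vector.
#' @examples
#' r <- setNames(rep(c(40, 60), 6), names(default_scale_items()))
#' score_dimensions(r)  # every dimension scores 50
#' @export
score_dimensions <- function(ratings, scale = mwl_scale()) {
  vec_in <- is.null(dim(ratings))
  if (vec_in) ratings <- matrix(ratings, nrow = 1L,
                                dimnames = list(NULL, names(ratings)))
  ratings <- as.matrix(ratings)
  need <- names(scale)
  miss <- setdiff(need, colnames(ratings))
  if (length(miss))
    stop("missing item rating(s): ", paste(miss, collapse = ", "))
  ratings <- ratings[, need, drop = FALSE]
  if (!is.numeric(ratings) || anyNA(ratings))
    stop("item ratings must be numeric and non-missing")
  if (any(ratings < 0 | ratings > 100))
    stop("item ratings must lie in [0, 100]")
  out <- vapply(mwl_dimensions(), function(d) {
    rowMeans(ratings[, names(scale)[scale == d], drop = FALSE])
  }, numeric(nrow(ratings)))
  if (nrow(ratings) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, mwl_dimensions()))
  if (vec_in) out[1L, ] else out
}

#' Derive per-respondent dimension weights from pairwise comparisons
#'
#' The weight of a dimension is the number of the 15 pairwise comparisons it
#' won, divided by 15. Weights therefore sum to exactly 1 and each weight is
#' k/15 for an integer k between 0 and 5.
#'
#' @param picks either a character vector of 15 winners named by canonical
#'   pair id (see [mwl_pairs()]), or a character matrix / data.frame with one
#'   row per respondent and one named column per pair; each entry names the
#'   winning dimension of that pair.
#' @return A numeric matrix (respondents x 6), or a named length-6 vector
#'   when `picks` was a vector.
#' @examples
#' p <- mwl_pairs()
#' w <- derive_weights(setNames(p$a, p$pair))  # first member always wins
#' sum(w)  # 1
#' @export
derive_weights <- function(picks) {
  vec_in <- is.null(dim(picks))
  if (vec_in) picks <- matrix(picks, nrow = 1L,
                              dimnames = list(NULL, names(picks)))
  picks <- as.matrix(picks)
  pairs <- mwl_pairs()
  miss <- setdiff(pairs$pair, colnames(picks))
  if (length(miss))
    stop("missing or duplicated pairwise comparison(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(colnames(picks)[colnames(picks) %in% pairs$pair]))
    stop("duplicated pairwise comparison column(s)")
  picks <- picks[, pairs$pair, drop = FALSE]
  if (anyNA(picks)) stop("pairwise picks must be non-missing")
  n <- nrow(picks)
  counts <- matrix(0L, n, 6L, dimnames = list(NULL, mwl_dimensions()))
  for (k in seq_len(15L)) {
    ok <- picks[, k] %in% c(pairs$a[k], pairs$b[k])
    if (!all(ok))
      stop("pick for pair '", pairs$pair[k],
           "' names a dimension outside the pair (row ",
           which(!ok)[1L], ")")
    for (d in c(pairs$a[k], pairs$b[k]))
      counts[, d] <- counts[, d] + (picks[, k] == d)
  }
  w <- counts / 15
  if (vec_in) w[1L, ] else w
}

#' Weighted total mental workload score
#'
#' The mental workload score (PMW) is the weight-weighted sum of the six
#' dimension scores. Because the weights are a convex combination, PMW is
#' bounded by the smallest and largest dimension scores and lies in
#' \[0, 100\].
#'
#' @param scores dimension scores as returned by [score_dimensions()]
#'   (vector or matrix).
#' @param weights dimension weights as returned by [derive_weights()]
#'   (conforming vector or matrix).
#' @return Numeric vector of PMW scores (length 1 for vector input).
#' @examples
#' s <- c(MD = 60, PD = 50, TD = 40, PR = 70, FL = 30, Pe = 80)
#' w <- c(MD = 5, PD = 4, TD = 3, PR = 2, FL = 1, Pe = 0) / 15
#' compute_pmw(s, w)
#' @export
compute_pmw <- function(scores, weights) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L,
                                             dimnames = list(NULL, names(scores)))
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1L,
                                               dimnames = list(NULL, names(weights)))
  dims <- mwl_dimensions()
  if (!all(dims %in% colnames(scores)) || !all(dims %in% colnames(weights)))
    stop("scores and weights must cover all six dimensions")
  scores <- as.matrix(scores[, dims, drop = FALSE])
  weights <- as.matrix(weights[, dims, drop = FALSE])
  if (nrow(scores) != nrow(weights))
    stop("scores and weights have different numbers of respondents")
  if (any(abs(rowSums(weights) - 1) > 1e-8))
    stop("weights must sum to 1 for every respondent")
  drop(rowSums(scores * weights))
}
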