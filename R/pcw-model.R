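#' Adjustment coefficient scheme
#'
#' The comprehensive workload index multiplies the summed task workloads by
#' three coefficients: objective workload (`r_ov`, driven by outpatients
#' served per day), patient complexity (`r_pc`, driven by the admitted-to-
#' seen ratio) and service quality (`r_ps`, driven by self-rated outpatient
#' satisfaction). The instrument fixes the inputs but not the scaling, so
#' each coefficient's normalisation is configurable and recorded in output
#' metadata.
#'
#' Defaults: `r_ov` divides by the sample mean (sample average workload maps
#' to 1); `r_pc` min-max normalises the admitted ratio over the sample and
#' adds 1, so a physician admitting no one sits exactly at the reference
#' value 1 and the coefficient lies in \[1, 2\]; `r_ps` divides by the scale
#' maximum 100.
#'
#' @param r_ov one of `"sample_mean"`, `"raw"`.
#' @param r_pc one of `"minmax1"` (min-max normalise, then add 1), `"raw1"`
#'   (raw ratio plus 1), `"raw"`.
#' @param r_ps one of `"scale_max"` (divide by 100), `"sample_mean"`,
#'   `"raw"`.
#' @return A named list of class `adjustment_scheme`.
#' @export
adjustment_scheme <- function(r_ov = c("sample_mean", "raw"),
                              r_pc = c("minmax1", "raw1", "raw"),
                              r_ps = c("scale_max", "sample_mean", "raw")) {
  out <- list(r_ov = match.arg(r_ov), r_pc = match.arg(r_pc),
              r_ps = match.arg(r_ps))
  class(out) <- "adjustment_scheme"
  out
}

#' Compute per-respondent adjustment coefficients
#'
#' @param data a `pcw_survey` data.frame with columns `n_outpatients`,
#'   `n_admitted` and `satisfaction`.
#' @param scheme an [adjustment_scheme()].
#' @return data.frame with columns `r_ov`, `r_pc`, `r_ps`, one row per
#'   respondent, with the scheme attached as attribute `scheme`. Records
#'   with zero outpatients per day are flagged in attribute `flagged` and
#'   get an admitted ratio of 0 (so `r_pc` sits at its floor of 1 under the
#'   default scheme).
#' @export
compute_adjustments <- function(data, scheme = adjustment_scheme()) {
  stopifnot(is.data.frame(data))
  n_out <- data$n_outpatients
  n_adm <- data$n_admitted
  sat <- data$satisfaction
  if (anyNA(n_out) || anyNA(n_adm) || anyNA(sat))
    stop("adjustment inputs contain missing values; screen with ",
         "validate_eligibility() first")
  if (any(n_adm > n_out))
    stop("admissions per day exceed outpatients per day for some records")
  flagged <- which(n_out == 0)
  ratio <- ifelse(n_out > 0, n_adm / n_out, 0)
  if (length(flagged))
    warning(length(flagged), " record(s) with zero outpatients per day; ",
            "admitted ratio treated as 0", call. = FALSE)

  r_ov <- switch(scheme$r_ov,
                 sample_mean = {
                   m <- mean(n_out)
                   if (m == 0) stop("sample mean of outpatients per day is 0")
                   n_out / m
                 },
                 raw = n_out)
  r_pc <- switch(scheme$r_pc,
                 minmax1 = {
                   rng <- range(ratio)
                   if (diff(rng) == 0) {
                     warning("admitted ratio is constant across the sample; ",
                             "all r_pc set to the reference value 1",
                             call. = FALSE)
                     rep(1, length(ratio))
                   } else (ratio - rng[1L]) / diff(rng) + 1
                 },
                 raw1 = ratio + 1,
                 raw = ratio)
  r_ps <- switch(scheme$r_ps,
                 scale_max = sat / 100,
                 sample_mean = {
                   m <- mean(sat)
                   if (m == 0) stop("sample mean satisfaction is 0")
                   sat / m
                 },
                 raw = sat)
  structure(data.frame(r_ov = r_ov, r_pc = r_pc, r_ps = r_ps),
            scheme = scheme, flagged = flagged)
}

#' Task-level workload: mental workload times time on task
#'
#' Workload tethered to a specific work task is the mental resources the
#' task consumes (the weighted mental workload score) multiplied by the time
#' the task requires (minutes per outpatient visit).
#'
#' @param pmw mental workload score(s) in \[0, 100\].
#' @param t minutes per visit, non-negative.
#' @return `pmw * t`, elementwise.
#' @export
compute_task_workload <- function(pmw, t) {
  if (any(!is.finite(pmw)) || any(pmw < 0 | pmw > 100))
    stop("pmw must be finite and in [0, 100]")
  if (any(!is.finite(t)) || any(t < 0))
    stop("task time must be finite and non-negative")
  pmw * t
}

#' Comprehensive workload index for one or more respondents
#'
#' The physician comprehensive workload (PCW) is the sum of the
#' communication and non-communication task workloads, multiplied by the
#' three adjustment coefficients:
#' `PCW = (pw_comm + pw_noncomm) * r_ov * r_pc * r_ps`.
#'
#' @param pw_comm,pw_noncomm task workloads from [compute_task_workload()].
#' @param coefficients data.frame with columns `r_ov`, `r_pc`, `r_ps` (as
#'   from [compute_adjustments()]), or a named list/vector of the three.
#' @return Numeric vector of PCW scores.
#' @export
compute_pcw <- function(pw_comm, pw_noncomm, coefficients) {
  co <- as.data.frame(as.list(coefficients))
  if (!all(c("r_ov", "r_pc", "r_ps") %in% names(co)))
    stop("coefficients must supply r_ov, r_pc and r_ps")
  if (any(pw_comm < 0) || any(pw_noncomm < 0) ||
      any(co$r_ov < 0) || any(co$r_pc < 0) || any(co$r_ps < 0))
    stop("all PCW inputs must be non-negative")
  (pw_comm + pw_noncomm) * co$r_ov * co$r_pc * co$r_ps
}

#' Mean +/- SD classification scheme for workload scores
#'
#' Cuts a score distribution at M - SD, M and M + SD into four groups:
#' I/low (score <= M - SD), II/medium (M - SD < score <= M), III/high
#' (M < score <= M + SD) and IV/very high (score > M + SD). Boundaries are
#' inclusive on the left of each cut.
#'
#' @param mean,sd centre and spread defining the cuts (`sd` is the sample
#'   standard deviation when derived from data).
#' @return List of class `pcw_classification` with elements `mean`, `sd`,
#'   `cut_low`, `cut_mid`, `cut_high`.
#' @examples
#' pcw_classification(811.30, 494.98)  # cuts 316.32 / 811.30 / 1306.28
#' @export
pcw_classification <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0)
  structure(list(mean = mean, sd = sd,
                 cut_low = mean - sd, cut_mid = mean,
                 cut_high = mean + sd),
            class = "pcw_classification")
}

#' @export
print.pcw_classification <- function(x, ...) {
  cat(sprintf("Workload classification: M = %.2f, SD = %.2f\n", x$mean, x$sd))
  cat(sprintf("  I/low        score <= %.2f\n", x$cut_low))
  cat(sprintf("  II/medium    %.2f < score <= %.2f\n", x$cut_low, x$cut_mid))
  cat(sprintf("  III/high     %.2f < score <= %.2f\n", x$cut_mid, x$cut_high))
  cat(sprintf("  IV/very high score > %.2f\n", x$cut_high))
  invisible(x)
}

#' Classify workload scores into the four groups
#'
#' When no scheme is supplied, the cuts are computed from the scores
#' themselves (sample mean and sample standard deviation). A degenerate
#' sample with zero spread yields all records in group II with a warning.
#'
#' @param scores numeric vector of non-negative workload scores.
#' @param scheme optional [pcw_classification()]; default derives one from
#'   `scores`.
#' @return List of class `pcw_types`: `scheme`, `type` (factor I--IV) and
#'   `group` (factor low/medium/high/very high), plus `counts` per group.
#' @export
classify_pcw <- function(scores, scheme = NULL) {
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("scores must be finite and non-negative")
  if (is.null(scheme)) {
    if (length(scores) < 2L)
      stop("need at least 2 scores to derive a classification scheme")
    scheme <- pcw_classification(mean(scores), stats::sd(scores))
  }
  stopifnot(inherits(scheme, "pcw_classification"))
  if (scheme$sd == 0) {
    warning("zero spread: all records classified as II/medium", call. = FALSE)
    type <- factor(rep("II", length(scores)), levels = c("I", "II", "III", "IV"))
  } else {
    cuts <- c(scheme$cut_low, scheme$cut_mid, scheme$cut_high)
    # absorb floating-point noise so a score printed equal to a cut point
    # falls on the <= side, as the boundary convention requires
    cuts <- cuts + 1e-9 * pmax(1, abs(cuts))
    idx <- findInterval(scores, cuts, left.open = TRUE) + 1L
    type <- factor(c("I", "II", "III", "IV")[idx],
                   levels = c("I", "II", "III", "IV"))
  }
  group <- factor(pcw_group_labels()[as.integer(type)],
                  levels = pcw_group_labels())
  structure(list(scheme = scheme, type = type, group = group,
                 counts = table(group)),
            class = "pcw_types")
}

#' @rdname classify_pcw
#' @export
pcw_group_labels <- function() c("low", "medium", "high", "very high")

#' @export
print.pcw_types <- function(x, ...) {
  print(x$scheme)
  n <- length(x$type)
  cnt <- x$counts
  cat("Group counts (N =", n, "):\n")
  for (g in names(cnt))
    cat(sprintf("  %-9s %5d (%.1f%%)\n", g, cnt[[g]], 100 * cnt[[g]] / n))
  invisible(x)
}

#' Distribution table of workload scores over fixed intervals
#'
#' Bins scores into left-open, right-closed intervals (the final interval is
#' right-open, capturing the upper tail), and reports counts, proportions
#' and cumulative proportions as percentages to one decimal.
#'
#' @param scores numeric vector of workload scores.
#' @param edges strictly increasing interval edges. The default spans 0 to
#'   1,800 in steps of 200 with a final open interval up to `upper`.
#' @param upper right end of the final (right-open) interval; defaults to
#'   the larger of 5,400 and the data maximum.
#' @param include_lowest if `TRUE`, a score equal to the first edge is
#'   counted in the first interval instead of raising an error.
#' @return data.frame of class `pcw_distribution` with columns `interval`,
#'   `n`, `proportion`, `cumulative`.
#' @export
distribution_table <- function(scores, edges = seq(0, 1800, by = 200),
                               upper = max(5400, max(scores) * 1.001),
                               include_lowest = FALSE) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing")
  if (upper <= edges[length(edges)])
    stop("upper must exceed the last edge")
  low <- scores < edges[1L] | (!include_lowest & scores == edges[1L])
  high <- scores >= upper
  if (any(low | high))
    stop("score(s) outside all bins: ",
         paste(utils::head(scores[low | high], 3L), collapse = ", "))
  all_edges <- c(edges, upper)
  k <- length(all_edges) - 1L
  idx <- findInterval(scores, all_edges, left.open = TRUE)
  idx[scores == edges[1L]] <- 1L  # reachable only when include_lowest
  counts <- tabulate(idx, nbins = k)
  labels <- c(sprintf("(%s,%s]", format(edges[-length(edges)], trim = TRUE),
                      format(edges[-1L], trim = TRUE)),
              sprintf("(%s,%s)", format(edges[length(edges)], trim = TRUE),
                      format(upper, trim = TRUE)))
  n <- length(scores)
  prop <- round(100 * counts / n, 1)
  cum <- round(100 * cumsum(counts) / n, 1)
  structure(data.frame(interval = labels, n = counts,
                       proportion = prop, cumulative = cum,
                       stringsAsFactors = FALSE),
            class = c("pcw_distribution", "data.frame"))
}
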