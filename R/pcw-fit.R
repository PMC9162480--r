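#' Fit the comprehensive workload index to a survey dataset
#'
#' `pcw()` is the package's central estimator. For each eligible respondent
#' it scores the mental workload scale for the communication and
#' non-communication task groups (dimension means weighted by the
#' respondent's own pairwise-comparison weights), multiplies each score by
#' the per-visit time of that task group, sums the two task workloads and
#' scales the sum by the three adjustment coefficients. The fitted object
#' carries the per-respondent results, the mean +/- SD classification into
#' the four workload groups, and the coefficient scheme metadata.
#'
#' Records whose index is exactly 0 (a zero factor in the product) are kept
#' in the results but their `ln_pcw` is `NA` and they are excluded from any
#' downstream log-scale regression, with a warning here.
#'
#' @param data a `pcw_survey` data.frame (see [read_survey()],
#'   [sample_population()]). Must already be eligibility-screened, or pass
#'   `screen = TRUE` to apply [validate_eligibility()] first.
#' @param scheme an [adjustment_scheme()].
#' @param scale an [mwl_scale()] item mapping.
#' @param screen apply the eligibility rules before fitting.
#' @return An object of class `pcw_fit`: a list with elements
#'   \describe{
#'     \item{results}{data.frame: `id`, `pmw_comm`, `pmw_noncomm`,
#'       `pw_comm`, `pw_noncomm`, `r_ov`, `r_pc`, `r_ps`, `pcw`, `ln_pcw`,
#'       `type`, `group`}
#'     \item{classification}{the [pcw_classification()] derived from the
#'       sample}
#'     \item{scheme}{the adjustment scheme used}
#'     \item{data}{the (screened) input data}
#'     \item{n}{number of respondents scored}
#'   }
#' @examples
#' cfg <- pcw_sim_config(n = 200)
#' fit <- pcw(sample_population(cfg, seed = 1))
#' fit
#' summary(fit)
#' @export
pcw <- function(data, scheme = adjustment_scheme(), scale = mwl_scale(),
                screen = FALSE) {
  stopifnot(is.data.frame(data))
  if (screen) data <- validate_eligibility(data)$eligible
  n <- nrow(data)
  if (n == 0L) stop("no records to score")
  items <- names(scale)
  score_group <- function(prefix) {
    ratings <- as.matrix(data[, paste0(prefix, "_", items), drop = FALSE])
    colnames(ratings) <- items
    picks <- as.matrix(data[, paste0(prefix, "_pick_", mwl_pairs()$pair),
                            drop = FALSE])
    colnames(picks) <- mwl_pairs()$pair
    compute_pmw(score_dimensions(ratings, scale), derive_weights(picks))
  }
  pmw_comm <- score_group("comm")
  pmw_noncomm <- score_group("noncomm")
  pw_comm <- compute_task_workload(pmw_comm, data$t_comm)
  pw_noncomm <- compute_task_workload(pmw_noncomm, data$t_noncomm)
  co <- compute_adjustments(data, scheme)
  pcw_score <- compute_pcw(pw_comm, pw_noncomm, co)
  zero <- pcw_score == 0
  if (any(zero))
    warning(sum(zero), " record(s) with PCW = 0; ln_pcw set to NA and ",
            "excluded from log-scale regression", call. = FALSE)
  ln_pcw <- ifelse(zero, NA_real_, log(pcw_score))
  cls <- classify_pcw(pcw_score)
  results <- data.frame(id = data$id,
                        pmw_comm = pmw_comm, pmw_noncomm = pmw_noncomm,
                        pw_comm = pw_comm, pw_noncomm = pw_noncomm,
                        r_ov = co$r_ov, r_pc = co$r_pc, r_ps = co$r_ps,
                        pcw = pcw_score, ln_pcw = ln_pcw,
                        type = cls$type, group = cls$group,
                        stringsAsFactors = FALSE)
  structure(list(results = results, classification = cls$scheme,
                 scheme = scheme, data = data, n = n),
            class = "pcw_fit")
}

#' @export
print.pcw_fit <- function(x, ...) {
  cat("Physician comprehensive workload fit\n")
  cat("  respondents:", x$n, "\n")
  cat(sprintf("  PCW: mean %.2f, SD %.2f, range [%.2f, %.2f]\n",
              x$classification$mean, x$classification$sd,
              min(x$results$pcw), max(x$results$pcw)))
  cat("  coefficient scheme: r_ov =", x$scheme$r_ov,
      "| r_pc =", x$scheme$r_pc, "| r_ps =", x$scheme$r_ps, "\n")
  cnt <- table(x$results$group)
  cat("  groups:", paste(sprintf("%s %d (%.1f%%)", names(cnt), cnt,
                                 100 * cnt / x$n), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pcw_fit <- function(object, ...) {
  r <- object$results
  out <- list(
    n = object$n,
    classification = object$classification,
    scheme = object$scheme,
    pcw = c(mean = mean(r$pcw), sd = stats::sd(r$pcw),
            min = min(r$pcw), max = max(r$pcw)),
    pmw = c(comm = mean(r$pmw_comm), noncomm = mean(r$pmw_noncomm)),
    groups = table(r$group),
    distribution = distribution_table(r$pcw, include_lowest = TRUE)
  )
  class(out) <- "summary.pcw_fit"
  out
}

#' @export
print.summary.pcw_fit <- function(x, ...) {
  cat("Physician comprehensive workload: summary of", x$n, "respondents\n\n")
  cat(sprintf("PCW mean %.2f (SD %.2f), range [%.2f, %.2f]\n",
              x$pcw["mean"], x$pcw["sd"], x$pcw["min"], x$pcw["max"]))
  cat(sprintf("Mental workload means: communication %.2f, non-communication %.2f\n\n",
              x$pmw["comm"], x$pmw["noncomm"]))
  print(x$classification)
  cat("\nGroup sizes:\n")
  print(x$groups)
  cat("\nScore distribution:\n")
  print.data.frame(x$distribution, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.pcw_fit <- function(x, ...) x$results

#' @export
plot.pcw_fit <- function(x, breaks = 30, ...) {
  r <- x$results
  graphics::hist(r$pcw, breaks = breaks, main = "Comprehensive workload",
                 xlab = "PCW score", col = "grey85", border = "white", ...)
  cl <- x$classification
  graphics::abline(v = c(cl$cut_low, cl$cut_mid, cl$cut_high),
                   lty = c(2, 1, 2), col = "firebrick")
  invisible(x)
}
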