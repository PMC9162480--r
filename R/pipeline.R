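#' Pipeline configuration
#'
#' Declares one full analysis run: the input (a survey CSV path or a
#' generator configuration, exactly one), the adjustment coefficient scheme,
#' the predictors and reference levels for the regression stages, and the
#' seed.
#'
#' The default predictors and reference levels mirror the reference
#' analysis: gender (ref Male), area (ref Central), weekly working hours
#' (ref >60) and weekly outpatient hours (ref <=8) for the log-scale
#' regression; the multinomial stage uses the same predictors with the
#' very-high workload group as base outcome.
#'
#' @param input path to a survey CSV, or `NULL`.
#' @param generator a [pcw_sim_config()], or `NULL`.
#' @param seed integer seed (used when generating).
#' @param scheme an [adjustment_scheme()].
#' @param predictors character vector of characteristic columns for the
#'   regression stages.
#' @param references named mapping predictor -> reference level.
#' @param base_outcome base workload group for the multinomial stage.
#' @return List of class `pcw_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL, seed = 1L,
                            scheme = adjustment_scheme(),
                            predictors = c("gender", "area",
                                           "hours_per_week",
                                           "outpatient_hours"),
                            references = list(gender = "Male",
                                              area = "Central",
                                              hours_per_week = ">60",
                                              outpatient_hours = "<=8"),
                            base_outcome = "very high") {
  if (is.null(input) == is.null(generator))
    stop("exactly one of input path / generator config must be set")
  structure(list(input = input, generator = generator, seed = seed,
                 scheme = scheme, predictors = predictors,
                 references = references, base_outcome = base_outcome),
            class = "pcw_pipeline_config")
}

# Table-1-style characteristics summary: count and percent per category.
characteristics_table <- function(data) {
  rows <- list()
  n <- nrow(data)
  for (v in names(survey_vocab())) {
    f <- factor(data[[v]], levels = survey_vocab()[[v]])
    cnt <- table(f)
    rows[[v]] <- data.frame(characteristic = v, category = names(cnt),
                            n = as.integer(cnt),
                            percent = round(100 * as.integer(cnt) / max(n, 1L), 1),
                            stringsAsFactors = FALSE)
  }
  num <- c("n_outpatients", "n_admitted", "satisfaction", "t_comm",
           "t_noncomm")
  nm <- do.call(rbind, lapply(num, function(v) data.frame(
    characteristic = v, category = "mean (SD)",
    n = NA_integer_,
    percent = NA_real_,
    stringsAsFactors = FALSE)))
  if (n > 0L)
    nm$category <- sprintf("%.2f (%.2f)",
                           vapply(num, function(v) mean(data[[v]]), 1),
                           vapply(num, function(v) stats::sd(data[[v]]), 1))
  do.call(rbind, c(rows, list(nm)))
}

#' Run the full analysis pipeline
#'
#' Executes read-or-generate, eligibility screening, scale scoring,
#' adjustment, comprehensive workload computation, classification,
#' distribution tabulation, per-characteristic cross-tabs with chi-square
#' tests, the log-scale linear regression and the multinomial regression.
#' Each stage is logged to stderr with its record count.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `pcw_report`: `characteristics` (summary table),
#'   `distribution`, `crosstabs` (per characteristic: counts, statistic,
#'   df, p), `regression` (`pcw_lm`), `multinomial` (`pcw_multinom`),
#'   `fit` (the underlying [pcw()] object), `eligibility`, `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pcw_pipeline_config"))
  stage <- function(...) message("[pcwload] ", ...)
  data <- if (!is.null(config$input)) {
    stage("reading survey: ", config$input)
    read_survey(config$input)
  } else {
    stage("generating survey: n = ", config$generator$n,
          ", seed = ", config$seed)
    sample_population(config$generator, seed = config$seed)
  }
  stage("eligibility screen on ", nrow(data), " records")
  elig <- validate_eligibility(data)
  stage(elig$n_eligible, " eligible (recovery rate ",
        ifelse(is.na(elig$recovery_rate), "n/a", elig$recovery_rate), "%)")
  if (elig$n_eligible == 0L) stop("pipeline aborted: no eligible records")
  fit <- pcw(elig$eligible, scheme = config$scheme)
  stage("scored ", fit$n, " respondents; PCW mean ",
        round(fit$classification$mean, 2))
  dist <- distribution_table(fit$results$pcw, include_lowest = TRUE)
  crosstabs <- lapply(config$predictors, function(p) {
    tab <- crosstab(fit$results$group, fit$data[[p]],
                    levels = survey_vocab()[[p]])
    # unobserved categories or groups carry no information for the test
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    ch <- chisq_pearson(tab)
    list(characteristic = p, counts = tab, statistic = ch$statistic,
         df = ch$df, p_value = ch$p_value)
  })
  names(crosstabs) <- config$predictors
  stage("chi-square tests on ", length(crosstabs), " characteristics")
  reg <- fit_lnpcw(fit, predictors = config$predictors,
                   references = config$references)
  stage("ln(PCW) regression on n = ", reg$n)
  mult <- fit_pcw_multinom(fit, predictors = config$predictors,
                           references = config$references,
                           base_outcome = config$base_outcome)
  stage("multinomial regression, base outcome '", config$base_outcome, "'")
  meta <- list(seed = config$seed,
               scheme = unclass(config$scheme),
               predictors = config$predictors,
               references = config$references,
               base_outcome = config$base_outcome,
               n_input = elig$n_input, n_eligible = elig$n_eligible,
               recovery_rate = elig$recovery_rate,
               provenance = attr(data, "provenance"))
  structure(list(characteristics = characteristics_table(fit$data),
                 distribution = dist, crosstabs = crosstabs,
                 regression = reg, multinomial = mult, fit = fit,
                 eligibility = elig, meta = meta),
            class = "pcw_report")
}

#' @export
print.pcw_report <- function(x, ...) {
  cat("Comprehensive workload analysis report\n")
  cat("  eligible respondents:", x$meta$n_eligible, "of", x$meta$n_input, "\n")
  cat(sprintf("  PCW mean %.2f (SD %.2f)\n", x$fit$classification$mean,
              x$fit$classification$sd))
  cat("  tables: characteristics, distribution,",
      length(x$crosstabs), "cross-tabs, regression, multinomial\n")
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Writes one CSV per table plus a `summary.json` with the run metadata,
#' group counts and headline statistics. Filenames are stable:
#' `characteristics.csv`, `distribution.csv`, `crosstabs.csv`,
#' `regression.csv`, `multinomial.csv`, `summary.json`.
#'
#' @param bundle a `pcw_report` from [run_pipeline()].
#' @param outdir output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "pcw_report"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  files <- character()
  w <- function(tab, name) {
    path <- file.path(outdir, name)
    write_table(tab, path)
    files <<- c(files, path)
  }
  w(bundle$characteristics, "characteristics.csv")
  w(bundle$distribution, "distribution.csv")
  ct <- do.call(rbind, lapply(bundle$crosstabs, function(x) {
    data.frame(characteristic = x$characteristic,
               category = rownames(x$counts),
               as.data.frame.matrix(x$counts),
               statistic = x$statistic, df = x$df, p_value = x$p_value,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(ct) <- NULL
  w(ct, "crosstabs.csv")
  w(bundle$regression$table, "regression.csv")
  w(bundle$multinomial$table, "multinomial.csv")
  cl <- bundle$fit$classification
  summary_json <- list(
    meta = bundle$meta,
    pcw = list(mean = cl$mean, sd = cl$sd,
               cuts = c(cl$cut_low, cl$cut_mid, cl$cut_high)),
    groups = as.list(table(bundle$fit$results$group))
  )
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, jp)
  invisible(files)
}
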