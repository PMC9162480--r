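#' Cross-tabulate workload groups against a characteristic
#'
#' @param groups factor (or vector) of per-respondent workload group labels.
#' @param characteristic per-respondent category vector of equal length.
#' @param levels optional explicit row ordering for the characteristic.
#' @return Integer matrix: characteristic categories (rows) by workload
#'   groups (columns).
#' @export
crosstab <- function(groups, characteristic, levels = NULL) {
  if (length(groups) != length(characteristic))
    stop("groups and characteristic have different lengths")
  if (anyNA(groups) || anyNA(characteristic))
    stop("complete cases required: missing group or characteristic values")
  if (!is.null(levels)) characteristic <- factor(characteristic, levels = levels)
  tab <- table(characteristic, groups)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Pearson chi-square test of independence
#'
#' Computes the classical statistic `sum((O - E)^2 / E)` with expected
#' counts `E = (row total * column total) / N`, degrees of freedom
#' `(r - 1)(c - 1)` and an asymptotic p-value, with no continuity
#' correction. The asymptotic distribution is used even when some expected
#' counts fall below 5; a warning flags that situation.
#'
#' @param table a matrix of non-negative counts (e.g. from [crosstab()]).
#' @return List of class `pcw_chisq`: `statistic`, `df`, `p_value`,
#'   `expected`, `n`.
#' @examples
#' chisq_pearson(rbind(c(10, 20), c(20, 10)))  # statistic 20/3
#' @export
chisq_pearson <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative and complete")
  n <- sum(m)
  if (n <= 0) stop("table total must be positive")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column marginal: expected counts undefined for ",
         paste(c(rownames(m)[rs == 0], colnames(m)[cs == 0]), collapse = ", "))
  e <- outer(rs, cs) / n
  if (any(e < 5))
    warning(sum(e < 5), " expected cell count(s) below 5; asymptotic ",
            "p-value may be unreliable", call. = FALSE)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = e, n = n),
            class = "pcw_chisq")
}

#' @export
print.pcw_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p %s\n",
              x$statistic, x$df, format_p(x$p_value)))
  invisible(x)
}

format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p))
}

# Significance flag at the reporting thresholds: '*' p < 0.10,
# '**' p < 0.05, '***' p < 0.01.
sig_flag <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                                        ifelse(p < 0.10, "*", ""))))
}

# Build an indicator-coded model frame with explicit reference levels.
# Returns list(frame, terms): frame has the response plus releveled factors.
build_design <- function(data, response, predictors, references) {
  frame <- data.frame(.y = data[[response]])
  for (p in predictors) {
    x <- data[[p]]
    if (is.null(x)) stop("predictor not found in data: ", p)
    lev <- if (!is.null(survey_vocab()[[p]])) survey_vocab()[[p]] else
      unique(as.character(x))
    lev <- lev[lev %in% unique(as.character(x))]
    f <- factor(as.character(x), levels = lev)
    ref <- references[[p]]
    if (!is.null(ref)) {
      if (!ref %in% levels(f))
        stop("reference level '", ref, "' absent from predictor ", p)
      f <- stats::relevel(f, ref = ref)
    }
    if (nlevels(f) < 2L)
      stop("predictor ", p, " has fewer than 2 observed levels")
    frame[[p]] <- f
  }
  frame
}

#' Multiple linear regression of log workload on characteristics
#'
#' Ordinary least squares of `ln(PCW)` on indicator-coded categorical
#' predictors with explicit reference levels, reporting the coefficient,
#' standard error, t statistic, p-value and variance inflation factor of
#' every non-reference term. Records with `PCW = 0` (undefined log) are
#' dropped.
#'
#' @param fit a [pcw()] object, or a data.frame containing `ln_pcw` plus the
#'   predictor columns.
#' @param predictors character vector of characteristic column names.
#' @param references named character vector/list mapping predictor to its
#'   reference level (defaults to the first vocabulary level).
#' @param data optional survey data.frame supplying predictor columns when
#'   `fit` is a `pcw_fit` (defaults to the data stored in the fit).
#' @return Object of class `pcw_lm`: `model` (the underlying `lm`),
#'   `table` (term-level summary with `vif`), `n`, `df`, `references`.
#' @export
fit_lnpcw <- function(fit, predictors, references = list(), data = NULL) {
  if (inherits(fit, "pcw_fit")) {
    if (is.null(data)) data <- fit$data
    stopifnot(nrow(data) == nrow(fit$results))
    df <- cbind(data, ln_pcw = fit$results$ln_pcw)
  } else df <- fit
  if (!"ln_pcw" %in% names(df)) stop("no ln_pcw column available")
  df <- df[is.finite(df$ln_pcw), , drop = FALSE]
  frame <- build_design(df, "ln_pcw", predictors, references)
  mod <- stats::lm(.y ~ ., data = frame)
  if (any(is.na(stats::coef(mod)))) {
    aliased <- names(stats::coef(mod))[is.na(stats::coef(mod))]
    stop("perfectly collinear design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(mod)$coefficients
  X <- stats::model.matrix(mod)[, -1L, drop = FALSE]
  # a single-column design has no companions to inflate against: VIF = 1
  vifs <- if (ncol(X) >= 2L) vif_terms(X) else
    stats::setNames(rep(1, ncol(X)), colnames(X))
  terms <- rownames(sm)
  tab <- data.frame(term = terms,
                    beta = sm[, 1L], se = sm[, 2L],
                    t = sm[, 3L], p_value = sm[, 4L],
                    vif = c(NA_real_, vifs[terms[-1L]]),
                    sig = sig_flag(sm[, 4L]),
                    stringsAsFactors = FALSE, row.names = NULL)
  refs <- vapply(predictors, function(p)
    levels(frame[[p]])[1L], character(1L))
  structure(list(model = mod, table = tab, n = nrow(frame),
                 df = mod$df.residual, references = refs),
            class = "pcw_lm")
}

#' @export
print.pcw_lm <- function(x, digits = 4, ...) {
  cat("ln(PCW) linear regression (n =", x$n, ", residual df =", x$df, ")\n")
  cat("Reference levels:",
      paste(names(x$references), x$references, sep = " = ", collapse = "; "),
      "\n\n")
  tab <- x$table
  tab$beta <- signif(tab$beta, digits); tab$se <- signif(tab$se, digits)
  tab$t <- round(tab$t, 2); tab$p_value <- signif(tab$p_value, 3)
  tab$vif <- round(tab$vif, 2)
  print.data.frame(tab, row.names = FALSE)
  cat("Significance: * p < 0.10, ** p < 0.05, *** p < 0.01\n")
  invisible(x)
}

#' @export
coef.pcw_lm <- function(object, ...) stats::coef(object$model)

#' Variance inflation factors of an indicator-coded design
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j on
#' all remaining columns. Computed per indicator column, matching per-term
#' reporting for dummy-coded categorical predictors.
#'
#' @param X numeric design matrix (no intercept column).
#' @return Named numeric vector of VIFs, one per column; an exactly
#'   collinear column yields `Inf` with a warning.
#' @examples
#' set.seed(1)
#' x1 <- rnorm(100); x2 <- rnorm(100)
#' vif_terms(cbind(x1, x2))  # ~1: orthogonal in expectation
#' @export
vif_terms <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 predictor columns for VIF")
  out <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1L))
  names(out) <- colnames(X)
  if (any(is.infinite(out)))
    warning("aliased (exactly collinear) term(s): ",
            paste(names(out)[is.infinite(out)], collapse = ", "),
            call. = FALSE)
  out
}

#' Multinomial logistic regression of workload group on characteristics
#'
#' Maximum-likelihood multinomial logit with a chosen base outcome,
#' reporting the relative risk ratio (exponentiated coefficient), Wald 95%
#' confidence interval (on the log scale, exponentiated) and p-value for
#' every non-reference term in every non-base outcome. A predictor level
#' with zero observations in some outcome cell is not estimable: its rows
#' are reported as `NA` rather than fitted values.
#'
#' @param fit a [pcw()] object, or a data.frame containing a `group` column
#'   plus predictor columns.
#' @param predictors character vector of characteristic column names.
#' @param references named mapping predictor -> reference level.
#' @param base_outcome the base workload group (default `"very high"`).
#' @param data optional data.frame of predictors when `fit` is a `pcw_fit`.
#' @param maxit maximum iterations for the optimiser.
#' @return Object of class `pcw_multinom`: `table` (outcome, term, rrr,
#'   ci_low, ci_high, p_value, estimable), `base_outcome`, `n`, `model`.
#' @export
fit_pcw_multinom <- function(fit, predictors, references = list(),
                             base_outcome = "very high", data = NULL,
                             maxit = 500) {
  if (inherits(fit, "pcw_fit")) {
    if (is.null(data)) data <- fit$data
    stopifnot(nrow(data) == nrow(fit$results))
    df <- cbind(data, group = fit$results$group)
  } else df <- fit
  if (!"group" %in% names(df)) stop("no group column available")
  y <- factor(as.character(df$group))
  if (!base_outcome %in% levels(y))
    stop("base outcome '", base_outcome, "' absent from data")
  y <- stats::relevel(y, ref = base_outcome)
  frame <- build_design(cbind(df, .out = y), ".out", predictors, references)
  names(frame)[1L] <- ".y"
  mod <- nnet::multinom(.y ~ ., data = frame, trace = FALSE, maxit = maxit,
                        Hess = TRUE)
  if (mod$convergence != 0)
    stop("multinomial fit did not converge after ", maxit, " iterations")
  cf <- stats::coef(mod)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L,
                                     dimnames = list(setdiff(levels(y), base_outcome),
                                                     mod$coefnames))
  V <- stats::vcov(mod)
  outcomes <- rownames(cf)
  terms <- colnames(cf)
  # cells with zero counts make the corresponding level not estimable
  bad_terms <- character()
  for (p in predictors) {
    tab <- table(frame[[p]], frame$.y)
    zero_lev <- rownames(tab)[apply(tab == 0, 1L, any)]
    if (length(zero_lev)) bad_terms <- c(bad_terms, paste0(p, zero_lev))
  }
  rows <- list()
  for (o in outcomes) for (tm in terms) {
    if (tm == "(Intercept)") next
    est <- !(tm %in% bad_terms)
    if (est) {
      b <- cf[o, tm]
      # with two outcome levels nnet drops the outcome prefix in vcov names
      vn <- if (length(outcomes) == 1L) tm else paste(o, tm, sep = ":")
      se <- sqrt(V[vn, vn])
      z <- b / se
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = o, term = tm, rrr = exp(b),
        ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
        p_value = 2 * stats::pnorm(-abs(z)), estimable = TRUE,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = o, term = tm, rrr = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, estimable = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$sig <- sig_flag(tab$p_value)
  structure(list(table = tab, base_outcome = base_outcome,
                 n = nrow(frame), model = mod),
            class = "pcw_multinom")
}

#' @export
print.pcw_multinom <- function(x, digits = 3, ...) {
  cat("Multinomial logistic regression (base outcome:", x$base_outcome,
      "; n =", x$n, ")\n\n")
  tab <- x$table
  fmt <- function(v) ifelse(is.na(v), "N/A", format(round(v, digits)))
  show <- data.frame(outcome = tab$outcome, term = tab$term,
                     RRR = fmt(tab$rrr),
                     `95% CI` = ifelse(tab$estimable,
                                       sprintf("(%s, %s)", fmt(tab$ci_low),
                                               fmt(tab$ci_high)), "N/A"),
                     p = ifelse(tab$estimable, sapply(tab$p_value, format_p),
                                "N/A"),
                     sig = tab$sig, check.names = FALSE)
  print.data.frame(show, row.names = FALSE)
  cat("Significance: * p < 0.10, ** p < 0.05, *** p < 0.01\n")
  invisible(x)
}
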