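#' Survey column schema and category vocabularies
#'
#' A survey file is UTF-8 comma-delimited text with one header row and one
#' row per respondent. Categorical characteristics are stored as the
#' canonical English tokens returned by `survey_vocab()`. The two working
#' hours characteristics may alternatively be supplied as raw numeric hours;
#' [read_survey()] bands them (left-open, right-closed) on read.
#'
#' Columns:
#' \describe{
#'   \item{id}{respondent identifier, unique within a file}
#'   \item{characteristics}{`gender`, `age_band`, `marital_status`,
#'     `education`, `income_band`, `title`, `tenure_band`, `area`,
#'     `hospital_level`, `hospital_nature`, `department`, `hours_per_week`,
#'     `outpatient_hours`, `health_status`}
#'   \item{eligibility}{`months_outpatient` (months worked in the outpatient
#'     clinic), `years_employed` (full-time years in the current
#'     institution)}
#'   \item{measurements}{`t_comm`, `t_noncomm` (minutes per visit),
#'     `n_outpatients`, `n_admitted` (per day), `satisfaction` (0--100)}
#'   \item{scale items}{`comm_<item>` and `noncomm_<item>` for the 12 item
#'     ids of [mwl_scale()] (ratings 0--100)}
#'   \item{pairwise picks}{`comm_pick_<pair>` and `noncomm_pick_<pair>` for
#'     the 15 pair ids of [mwl_pairs()] (each the winning dimension code)}
#' }
#'
#' @return `survey_columns()`: character vector of all column names in
#'   canonical order. `survey_vocab()`: named list of category vocabularies.
#' @export
survey_columns <- function() {
  items <- names(default_scale_items())
  pairs <- mwl_pairs()$pair
  c("id", names(survey_vocab()),
    "months_outpatient", "years_employed",
    "t_comm", "t_noncomm", "n_outpatients", "n_admitted", "satisfaction",
    paste0("comm_", items), paste0("comm_pick_", pairs),
    paste0("noncomm_", items), paste0("noncomm_pick_", pairs))
}

#' @rdname survey_columns
#' @export
survey_vocab <- function() {
  list(
    gender = c("Male", "Female"),
    age_band = c("20-30", "31-40", "41-55", ">55"),
    marital_status = c("Unmarried", "Married", "Divorced", "Widowed"),
    education = c("Doctorate", "Master", "Undergraduate", "Junior college",
                  "Others"),
    income_band = c("<=5000", "5001-10000", "10001-15000", ">15000"),
    title = c("Senior", "Associate senior", "Intermediate", "Junior",
              "Others"),
    tenure_band = c("1-5", "6-10", "11-15", "16-20", ">20"),
    area = c("Eastern", "Central", "Western"),
    hospital_level = c("Tertiary A", "Tertiary B", "Secondary", "First-tier"),
    hospital_nature = c("Public general", "Public specialized",
                        "Private general", "Private specialized"),
    department = c("Internal", "Surgical", "Obstetrics and gynecology",
                   "Pediatrics", "Others"),
    hours_per_week = c("<=40", "41-60", ">60"),
    outpatient_hours = c("<=8", "~16", "~24", "~40", ">40"),
    health_status = c("Very poor", "Poor", "Fair", "Good", "Very good")
  )
}

# Band raw weekly hours using the instrument's boundaries (left-open,
# right-closed). Values already coded as band tokens pass through verbatim.
band_hours <- function(x, which = c("hours_per_week", "outpatient_hours")) {
  which <- match.arg(which)
  vocab <- survey_vocab()[[which]]
  out <- as.character(x)
  num <- suppressWarnings(as.numeric(out))
  is_num <- !is.na(num)
  if (any(is_num)) {
    if (which == "hours_per_week") {
      out[is_num] <- vocab[findInterval(num[is_num], c(-Inf, 40, 60),
                                        left.open = TRUE)]
    } else {
      out[is_num] <- vocab[findInterval(num[is_num], c(-Inf, 8, 16, 24, 40),
                                        left.open = TRUE)]
    }
  }
  out
}

#' Read a survey file
#'
#' Reads a delimited survey file with the schema of [survey_columns()],
#' normalises hour columns (numeric values are banded), and validates each
#' row. Malformed rows are kept in the returned dataset but every problem is
#' recorded in the `problems` attribute (a data.frame of `row`, `id`,
#' `field`, `problem`) and reported with a warning; [validate_eligibility()]
#' later rejects such rows explicitly.
#'
#' @param path path to a UTF-8 CSV file.
#' @return A `pcw_survey` data.frame with attributes `provenance` (the source
#'   path) and `problems`.
#' @seealso [write_table()], [validate_eligibility()]
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  miss <- setdiff(survey_columns(), names(df))
  if (length(miss))
    stop("survey file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, survey_columns(), drop = FALSE]
  df[df == ""] <- NA
  as_survey(df, provenance = path)
}

# Validate and type a raw character data.frame into a pcw_survey.
as_survey <- function(df, provenance = "in-memory") {
  problems <- list()
  note <- function(rows, field, what) {
    if (length(rows))
      problems[[length(problems) + 1L]] <<- data.frame(
        row = rows, id = as.character(df$id[rows]), field = field,
        problem = what, stringsAsFactors = FALSE)
  }
  df$hours_per_week <- band_hours(df$hours_per_week, "hours_per_week")
  df$outpatient_hours <- band_hours(df$outpatient_hours, "outpatient_hours")
  vocab <- survey_vocab()
  for (v in names(vocab)) {
    bad <- which(!is.na(df[[v]]) & !(df[[v]] %in% vocab[[v]]))
    note(bad, v, "value outside category vocabulary")
    df[[v]][bad] <- NA
  }
  num_cols <- c("months_outpatient", "years_employed", "t_comm", "t_noncomm",
                "n_outpatients", "n_admitted", "satisfaction",
                grep("^(comm|noncomm)_(md|pd|td|pr|fl|pe)[12]$",
                     survey_columns(), value = TRUE))
  for (v in num_cols) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    note(which(!is.na(raw) & is.na(num)), v, "unparseable numeric")
    df[[v]] <- num
  }
  for (v in c("t_comm", "t_noncomm", "n_outpatients", "n_admitted",
              "months_outpatient", "years_employed")) {
    bad <- which(!is.na(df[[v]]) & (df[[v]] < 0 | !is.finite(df[[v]])))
    note(bad, v, "negative or non-finite")
    df[[v]][bad] <- NA
  }
  bad <- which(!is.na(df$satisfaction) &
                 (df$satisfaction < 0 | df$satisfaction > 100))
  note(bad, "satisfaction", "outside [0, 100]")
  df$satisfaction[bad] <- NA
  bad <- which(!is.na(df$n_admitted) & !is.na(df$n_outpatients) &
                 df$n_admitted > df$n_outpatients)
  note(bad, "n_admitted", "admissions exceed outpatients seen")
  rate_cols <- grep("^(comm|noncomm)_(md|pd|td|pr|fl|pe)[12]$",
                    names(df), value = TRUE)
  for (v in rate_cols) {
    bad <- which(!is.na(df[[v]]) & (df[[v]] < 0 | df[[v]] > 100))
    note(bad, v, "rating outside [0, 100]")
    df[[v]][bad] <- NA
  }
  if (anyDuplicated(df$id))
    stop("respondent ids are not unique: e.g. ",
         df$id[anyDuplicated(df$id)])
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), id = character(), field = character(),
               problem = character(), stringsAsFactors = FALSE)
  if (nrow(problems))
    warning(nrow(problems), " malformed value(s) in ", provenance,
            "; see attr(, 'problems')", call. = FALSE)
  structure(df, class = c("pcw_survey", "data.frame"),
            provenance = provenance, problems = problems)
}

#' Apply the study eligibility rules
#'
#' A respondent is eligible if they have worked at least 4 months in the
#' outpatient clinic, have been employed full-time for at least 1 year in
#' their current institution, and have no missing or malformed value in any
#' field the pipeline uses (complete-case analysis). The effective recovery
#' rate is the eligible count over the input count, as a percentage.
#'
#' @param data a `pcw_survey` data.frame from [read_survey()] or
#'   [sample_population()].
#' @return A list of class `pcw_eligibility`:
#'   \describe{
#'     \item{eligible}{the eligible subset (a `pcw_survey`)}
#'     \item{rejections}{data.frame of `id`, `rule` for each rejected record}
#'     \item{n_input, n_eligible}{counts}
#'     \item{recovery_rate}{percent to 1 decimal; `NA` for empty input}
#'   }
#' @export
validate_eligibility <- function(data) {
  stopifnot(is.data.frame(data))
  problems <- attr(data, "problems")
  bad_ids <- if (!is.null(problems)) unique(problems$id) else character()
  rules <- list(
    `tenure<4 months` = function(d)
      is.na(d$months_outpatient) | d$months_outpatient < 4,
    `employment<1 year` = function(d)
      is.na(d$years_employed) | d$years_employed < 1,
    `malformed field` = function(d) d$id %in% bad_ids,
    `incomplete record` = function(d)
      rowSums(is.na(d[, setdiff(names(d), "id"), drop = FALSE])) > 0
  )
  rej <- data.frame(id = character(), rule = character(),
                    stringsAsFactors = FALSE)
  rejected <- rep(FALSE, nrow(data))
  for (r in names(rules)) {
    hit <- rules[[r]](data) & !rejected
    if (any(hit))
      rej <- rbind(rej, data.frame(id = as.character(data$id[hit]), rule = r,
                                   stringsAsFactors = FALSE))
    rejected <- rejected | rules[[r]](data)
  }
  eligible <- data[!rejected, , drop = FALSE]
  attr(eligible, "provenance") <- attr(data, "provenance")
  attr(eligible, "problems") <- problems[0, ]
  class(eligible) <- class(data)
  n <- nrow(data)
  out <- list(eligible = eligible, rejections = rej,
              n_input = n, n_eligible = nrow(eligible),
              recovery_rate = if (n == 0L) NA_real_ else
                round(100 * nrow(eligible) / n, 1))
  class(out) <- "pcw_eligibility"
  out
}

#' @export
print.pcw_eligibility <- function(x, ...) {
  cat("Survey eligibility screen\n")
  cat("  input records:   ", x$n_input, "\n")
  cat("  eligible records:", x$n_eligible, "\n")
  cat("  recovery rate:   ",
      if (is.na(x$recovery_rate)) "not applicable (empty input)"
      else paste0(x$recovery_rate, "%"), "\n")
  if (nrow(x$rejections)) {
    cat("  rejections by rule:\n")
    print(table(x$rejections$rule))
  }
  invisible(x)
}

#' Write a tabular result as delimited text
#'
#' Writes any named-column table as CSV with a stable column order so that
#' re-reading yields equal values. The inverse of [read_survey()] for survey
#' datasets, and the serializer used by [render_reports()] for all report
#' tables.
#'
#' @param table a data.frame (or coercible) with named columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  table <- as.data.frame(table)
  if (is.null(names(table)) || any(names(table) == ""))
    stop("table must have named columns")
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
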