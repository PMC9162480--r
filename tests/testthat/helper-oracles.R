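# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use explicit loops and first-principles
# arithmetic, not the package's vectorised implementations.

# Weighted mental workload by explicit loops over items and picks.
oracle_pmw <- function(ratings, picks, mapping = default_scale_items()) {
  dims <- unique(unname(mapping))
  dim_score <- sapply(dims, function(d) {
    its <- names(mapping)[mapping == d]
    s <- 0
    for (it in its) s <- s + ratings[[it]]
    s / length(its)
  })
  wins <- setNames(rep(0, length(dims)), dims)
  for (p in names(picks)) wins[[picks[[p]]]] <- wins[[picks[[p]]]] + 1
  total <- 0
  for (d in dims) total <- total + dim_score[[d]] * wins[[d]] / 15
  total
}

# Pearson chi-square by explicit double loop.
oracle_chisq <- function(m) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / n
    stat <- stat + (m[i, j] - e)^2 / e
  }
  stat
}

# A valid random assessment: ratings on the 0-100 scale and one winner per
# dimension pair.
random_assessment <- function() {
  items <- names(default_scale_items())
  ratings <- setNames(sample(seq(0, 100, by = 10), 12, replace = TRUE), items)
  pairs <- mwl_pairs()
  picks <- setNames(ifelse(runif(15) < 0.5, pairs$a, pairs$b), pairs$pair)
  list(ratings = ratings, picks = picks)
}

# A tiny fully-valid survey data.frame built by hand (n rows), with every
# schema column present and eligibility satisfied.
make_survey <- function(n = 3) {
  vocab <- survey_vocab()
  df <- data.frame(id = paste0("p", seq_len(n)), stringsAsFactors = FALSE)
  for (v in names(vocab)) df[[v]] <- rep_len(vocab[[v]], n)
  df$months_outpatient <- rep(12, n)
  df$years_employed <- rep(5, n)
  df$t_comm <- seq(4, by = 1, length.out = n)
  df$t_noncomm <- seq(2, by = 1, length.out = n)
  df$n_outpatients <- rep(40, n)
  df$n_admitted <- seq(0, by = 2, length.out = n)
  df$satisfaction <- rep(80, n)
  items <- names(default_scale_items())
  pairs <- mwl_pairs()
  for (tg in c("comm", "noncomm")) {
    for (k in seq_along(items))
      df[[paste0(tg, "_", items[k])]] <- rep(((k - 1) %% 11) * 10, n)
    for (k in seq_len(15))
      df[[paste0(tg, "_pick_", pairs$pair[k])]] <- rep(pairs$a[k], n)
  }
  df[, survey_columns()]
}

# Type and validate a hand-built data.frame as read_survey would.
as_survey_for_test <- function(df) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_table(df, path)
  read_survey(path)
}

ref_group_sizes <- function() {
  tab <- reference_crosstabs("gender")
  colSums(tab)
}
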