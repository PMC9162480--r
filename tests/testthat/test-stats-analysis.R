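test_that("crosstab counts cells and ignores record order", {
  g <- c("low", "medium", "high", "very high")
  tab <- crosstab(factor(g, levels = g), rep("Female", 4))
  expect_equal(dim(tab), c(1L, 4L))
  expect_true(all(tab == 1))

  set.seed(91)
  groups <- sample(g, 200, replace = TRUE)
  chars <- sample(c("A", "B", "C"), 200, replace = TRUE)
  t1 <- crosstab(groups, chars)
  perm <- sample(200)
  expect_equal(crosstab(groups[perm], chars[perm]), t1)
  expect_equal(sum(t1), 200)
  expect_error(crosstab(groups, chars[-1]), "length")
})

test_that("chi-square matches closed forms and rejects empty marginals", {
  res <- chisq_pearson(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$statistic, 20 / 3)
  expect_equal(res$df, 1)
  # proportional rows: observed equals expected, statistic 0
  res0 <- chisq_pearson(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(chisq_pearson(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("chi-square equals the brute-force oracle on random tables", {
  set.seed(101)
  for (i in 1:500) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    m <- matrix(sample(1:80, nr * nc, replace = TRUE), nr, nc)
    res <- suppressWarnings(chisq_pearson(m))
    expect_lt(abs(res$statistic - oracle_chisq(m)), 1e-9)
    # invariance under row/column permutation and transposition
    mp <- m[sample(nr), sample(nc)]
    expect_equal(suppressWarnings(chisq_pearson(mp))$statistic,
                 res$statistic)
    expect_equal(suppressWarnings(chisq_pearson(t(m)))$statistic,
                 res$statistic)
  }
})

test_that("chi-square agrees with the uncorrected textbook test", {
  set.seed(111)
  for (i in 1:25) {
    m <- matrix(sample(5:60, 12, replace = TRUE), 3, 4)
    ours <- suppressWarnings(chisq_pearson(m))
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("noiseless log-workload data are recovered to machine precision", {
  n <- 400
  gender <- rep(c("Male", "Female"), each = n / 2)
  df <- data.frame(gender = gender,
                   ln_pcw = 6.353 + 0.115 * (gender == "Female"))
  reg <- suppressWarnings(fit_lnpcw(df, predictors = "gender",
                                    references = list(gender = "Male")))
  expect_equal(reg$table$beta[reg$table$term == "(Intercept)"], 6.353,
               tolerance = 1e-12)
  expect_equal(reg$table$beta[reg$table$term == "genderFemale"], 0.115,
               tolerance = 1e-12)
  # translation equivariance: shifting the response moves only the intercept
  df2 <- df; df2$ln_pcw <- df$ln_pcw + 1.7
  reg2 <- suppressWarnings(fit_lnpcw(df2, "gender", list(gender = "Male")))
  expect_equal(reg2$table$beta[1], reg$table$beta[1] + 1.7)
  expect_equal(reg2$table$beta[-1], reg$table$beta[-1])
})

test_that("regression estimates converge to generating values with n", {
  set.seed(121)
  truth <- 0.25
  err <- sapply(c(500, 2000, 8000), function(n) {
    g <- sample(c("Male", "Female"), n, replace = TRUE)
    df <- data.frame(gender = g,
                     ln_pcw = 6 + truth * (g == "Female") + rnorm(n, 0, 0.7))
    reg <- fit_lnpcw(df, "gender", list(gender = "Male"))
    abs(reg$table$beta[reg$table$term == "genderFemale"] - truth)
  })
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1] + 0.02)  # shrinking error, up to sampling noise
})

test_that("VIF matches its closed form and flags aliasing", {
  set.seed(131)
  n <- 4000
  # orthogonal-by-construction predictors
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  v <- vif_terms(cbind(x1, x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12)
  # correlation 0.8 -> VIF = 1 / (1 - 0.64) = 2.778 for both
  S <- chol(matrix(c(1, .8, .8, 1), 2))
  X <- matrix(rnorm(2 * n), ncol = 2) %*% S
  r <- cor(X[, 1], X[, 2])
  v <- vif_terms(X)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-9)
  expect_equal(unname(v), rep(2.778, 2), tolerance = 0.15)
  w <- capture_warnings(vd <- vif_terms(cbind(x1, x1, x2)))
  expect_true(any(grepl("aliased", w)))
  expect_true(is.infinite(vd[1]))
})

test_that("regression reports per-term VIF and errors on exact collinearity", {
  set.seed(141)
  n <- 600
  df <- data.frame(
    gender = sample(c("Male", "Female"), n, replace = TRUE),
    area = sample(c("Eastern", "Central", "Western"), n, replace = TRUE))
  df$ln_pcw <- 6 + 0.2 * (df$gender == "Female") + rnorm(n, 0, 0.5)
  reg <- fit_lnpcw(df, c("gender", "area"),
                   list(gender = "Male", area = "Central"))
  expect_true(all(reg$table$vif[-1] >= 1))
  expect_equal(nrow(reg$table), 4)  # intercept + female + 2 area terms
  df$copy <- df$gender
  expect_error(suppressWarnings(
    fit_lnpcw(df, c("gender", "copy"),
              list(gender = "Male", copy = "Male"))), "collinear")
})

test_that("collapsed two-group multinomial equals the 2x2 odds ratio", {
  set.seed(151)
  n <- 2000
  g <- sample(c("Male", "Female"), n, replace = TRUE)
  p <- ifelse(g == "Female", 0.65, 0.45)
  grp <- ifelse(runif(n) < p, "very high", "low")
  df <- data.frame(gender = g, group = grp, stringsAsFactors = FALSE)
  fit <- fit_pcw_multinom(df, "gender", list(gender = "Male"),
                          base_outcome = "very high")
  tab2 <- table(df$gender, df$group)
  or <- (tab2["Female", "low"] * tab2["Male", "very high"]) /
    (tab2["Female", "very high"] * tab2["Male", "low"])
  row <- fit$table[fit$table$term == "genderFemale", ]
  expect_equal(row$rrr, unname(or), tolerance = 1e-4)
  expect_true(row$ci_low < row$rrr && row$rrr < row$ci_high)
})

test_that("null predictors give near-unity RRRs at nominal error rates", {
  set.seed(161)
  reps <- 60
  logrrr <- reject <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    n <- 5000
    df <- data.frame(
      gender = sample(c("Male", "Female"), n, replace = TRUE),
      group = sample(pcw_group_labels(), n, replace = TRUE,
                     prob = c(.12, .45, .31, .12)))
    fit <- fit_pcw_multinom(df, "gender", list(gender = "Male"))
    rows <- fit$table[fit$table$term == "genderFemale", ]
    logrrr[i, ] <- log(rows$rrr)
    reject[i, ] <- rows$p_value < 0.05
  }
  # per-term: type-I error near nominal 5%, log RRR centred on 0
  expect_true(all(colMeans(reject) <= 0.15))
  expect_true(all(abs(colMeans(logrrr)) < 0.05))
  expect_gte(mean(rowSums(reject) == 0), 0.75)  # most replicates fully null
})

test_that("empty outcome cells are reported as not estimable", {
  set.seed(171)
  n <- 300
  df <- data.frame(
    hospital_level = sample(c("Tertiary A", "Secondary", "First-tier"), n,
                            replace = TRUE, prob = c(.6, .35, .05)),
    group = sample(pcw_group_labels(), n, replace = TRUE))
  df$group[df$hospital_level == "First-tier"] <- "low"  # zero cells elsewhere
  fit <- fit_pcw_multinom(df, "hospital_level",
                          list(hospital_level = "Tertiary A"))
  ft <- fit$table[fit$table$term == "hospital_levelFirst-tier", ]
  expect_true(all(!ft$estimable))
  expect_true(all(is.na(ft$rrr)))
  other <- fit$table[fit$table$term == "hospital_levelSecondary", ]
  expect_true(all(other$estimable))
})
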