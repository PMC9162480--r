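test_that("generation is deterministic given config and seed", {
  cfg <- pcw_sim_config(n = 60)
  a <- sample_population(cfg, seed = 7)
  b <- sample_population(cfg, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sample_population(cfg, seed = 8)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(pcw_sim_config(n = 10, marginals = list(gender = c(Male = 0.7,
                                                                  Female = 0.2))),
               "sum to 1")
  expect_error(pcw_sim_config(n = 10, effects = list(shoe_size = c(a = 1))),
               "unknown characteristic")
  expect_error(pcw_sim_config(n = 10, effects = list(gender = 0.1)),
               "named")
})

test_that("generated records satisfy the survey invariants", {
  cfg <- pcw_sim_config(n = 800)
  dat <- sample_population(cfg, seed = 17)
  expect_s3_class(dat, "pcw_survey")
  expect_equal(nrow(attr(dat, "problems")), 0)
  expect_true(all(dat$n_admitted <= dat$n_outpatients))
  expect_true(all(dat$satisfaction >= 0 & dat$satisfaction <= 100))
  expect_true(all(dat$satisfaction %% 5 == 0))
  items <- grep("^comm_(md|pd|td|pr|fl|pe)", names(dat), value = TRUE)
  items <- items[!grepl("pick", items)]
  for (it in items) expect_true(all(dat[[it]] %% 10 == 0))
  expect_true(all(dat$t_comm > 0) && all(dat$t_noncomm > 0))
  # all records are generated eligible
  elig <- validate_eligibility(dat)
  expect_equal(elig$n_eligible, 800)
})

test_that("large samples reproduce the configured marginal structure", {
  cfg <- pcw_sim_config(n = 20000)
  dat <- sample_population(cfg, seed = 27)
  target_female <- default_marginals()$gender[["Female"]]
  expect_lt(abs(100 * mean(dat$gender == "Female") - 100 * target_female), 1.5)
  expect_lt(abs(mean(dat$n_outpatients) - 43.20), 0.5)
  expect_lt(abs(sd(dat$n_outpatients) - 24.81), 1.5)
  expect_lt(abs(mean(dat$n_admitted) - 4.22), 0.25)
  expect_lt(abs(mean(dat$satisfaction) - 80.59), 1.0)
})

test_that("category frequencies are consistent with the configured
           probabilities by goodness of fit", {
  cfg <- pcw_sim_config(n = 50000)
  dat <- sample_population(cfg, seed = 37)
  for (v in c("gender", "area", "department", "hospital_level")) {
    p <- default_marginals()[[v]]
    obs <- table(factor(dat[[v]], levels = names(p)))
    gof <- stats::chisq.test(as.integer(obs), p = as.numeric(p))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("injected covariate effects shift the latent workload scale", {
  cfg <- pcw_sim_config(n = 4000, effects = list(gender = c(Female = 0.5)))
  dat <- sample_population(cfg, seed = 47)
  eta <- attr(dat, "latent")
  gap <- mean(eta[dat$gender == "Female"]) - mean(eta[dat$gender == "Male"])
  expect_equal(gap, 0.5, tolerance = 0.1)
  # and it propagates into the fitted index; a shift this large pushes some
  # ratings into the scale ceiling, so mild attenuation is expected
  fit <- suppressWarnings(pcw(dat))
  reg <- fit_lnpcw(fit, "gender", list(gender = "Male"))
  beta <- reg$table$beta[reg$table$term == "genderFemale"]
  expect_gt(beta, 0.35)
  expect_lt(beta, 0.55)
})

test_that("recovery experiment reports bias, coverage and failures", {
  cfg <- pcw_sim_config(n = 600, effects = list(gender = c(Female = 0.115)))
  rec <- recovery_experiment(cfg, replicates = 12, seed = 100,
                             references = list(gender = "Male"))
  expect_equal(rec$failures, 0)
  expect_equal(dim(rec$estimates), c(12L, 1L))
  s <- rec$summary
  expect_equal(s$term, "genderFemale")
  expect_equal(s$truth, 0.115)
  expect_lt(abs(s$bias), 0.1)  # loose at 12 replicates; tight case elsewhere
  expect_true(s$coverage >= 0 && s$coverage <= 1)
})

test_that("zero-effect configurations give nominal interval coverage", {
  cfg <- pcw_sim_config(n = 400, effects = list(gender = c(Female = 0)))
  rec <- recovery_experiment(cfg, replicates = 60, seed = 200,
                             references = list(gender = "Male"))
  expect_gte(rec$summary$coverage, 0.85)
  expect_lte(rec$summary$coverage, 1.0)
})
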