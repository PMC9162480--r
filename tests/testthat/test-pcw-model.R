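adj_data <- function(n_out, n_adm, sat) {
  data.frame(n_outpatients = n_out, n_admitted = n_adm, satisfaction = sat)
}

test_that("patient-complexity coefficient: min-max normalised ratio plus 1", {
  d <- adj_data(c(10, 10, 10), c(0, 1, 2), c(80, 80, 80))  # ratios 0/.1/.2
  co <- compute_adjustments(d)
  expect_equal(co$r_pc, c(1.0, 1.5, 2.0))
  # zero admissions sit exactly at the reference value 1
  expect_equal(co$r_pc[1], 1)
  expect_true(all(co$r_pc >= 1 & co$r_pc <= 2))
})

test_that("objective-workload coefficient divides by the sample mean", {
  d <- adj_data(c(20, 40, 60), c(0, 0, 0), c(100, 50, 75))
  expect_warning(co <- compute_adjustments(d), "constant")
  expect_equal(co$r_ov, c(0.5, 1.0, 1.5))
  expect_equal(co$r_ps, c(1.0, 0.5, 0.75))  # divide by scale max 100
  expect_equal(co$r_pc, c(1, 1, 1))         # degenerate min-max -> reference
})

test_that("alternative coefficient schemes are honoured", {
  d <- adj_data(c(20, 40), c(2, 10), c(60, 90))
  co <- compute_adjustments(d, adjustment_scheme(r_ov = "raw", r_pc = "raw",
                                                 r_ps = "raw"))
  expect_equal(co$r_ov, c(20, 40))
  expect_equal(co$r_pc, c(0.1, 0.25))
  expect_equal(co$r_ps, c(60, 90))
  co2 <- compute_adjustments(d, adjustment_scheme(r_pc = "raw1",
                                                  r_ps = "sample_mean"))
  expect_equal(co2$r_pc, c(1.1, 1.25))
  expect_equal(co2$r_ps, c(60, 90) / 75)
})

test_that("zero-outpatient records are flagged with ratio treated as 0", {
  d <- adj_data(c(0, 10, 20), c(0, 1, 4), c(80, 80, 80))
  expect_warning(co <- compute_adjustments(d), "zero outpatients")
  expect_equal(attr(co, "flagged"), 1L)
  expect_equal(co$r_pc[1], 1)  # floor at the reference value
})

test_that("task workload multiplies mental workload by time on task", {
  expect_equal(compute_task_workload(60, 6), 360)
  expect_equal(compute_task_workload(85, 0), 0)
  expect_equal(compute_task_workload(0, 42), 0)
  expect_error(compute_task_workload(50, -1), "non-negative")
  expect_error(compute_task_workload(130, 1), "\\[0, 100\\]")
})

test_that("the comprehensive index is the adjusted task-workload sum", {
  co <- list(r_ov = 1.0, r_pc = 1.2, r_ps = 0.8)
  expect_equal(compute_pcw(360, 200, co), 537.6)
  expect_equal(compute_pcw(360, 200, co), (360 + 200) * 1.0 * 1.2 * 0.8)
  expect_equal(compute_pcw(300, 100, list(r_ov = 1, r_pc = 1, r_ps = 1)), 400)
  expect_equal(compute_pcw(0, 0, co), 0)
  # strictly increasing in each argument when the others are positive
  expect_gt(compute_pcw(361, 200, co), compute_pcw(360, 200, co))
  expect_gt(compute_pcw(360, 200, list(r_ov = 1.1, r_pc = 1.2, r_ps = 0.8)),
            compute_pcw(360, 200, co))
})

test_that("classification follows the printed boundary convention", {
  sch <- pcw_classification(811.30, 494.98)
  expect_equal(sch$cut_low, 316.32)
  expect_equal(sch$cut_high, 1306.28)
  cls <- classify_pcw(c(300, 316.32, 316.33, 811.30, 811.31, 1306.28,
                        1306.29, 1500), scheme = sch)
  expect_equal(as.character(cls$type),
               c("I", "I", "II", "II", "III", "III", "IV", "IV"))
  expect_equal(as.character(cls$group[c(1, 8)]), c("low", "very high"))
})

test_that("degenerate zero-spread samples classify as medium with a warning", {
  expect_warning(cls <- classify_pcw(rep(500, 10)), "zero spread")
  expect_true(all(cls$type == "II"))
})

test_that("classification partitions the sample and is scale-equivariant", {
  set.seed(61)
  scores <- rlnorm(400, log(600), 0.5)
  cls <- classify_pcw(scores)
  expect_equal(sum(cls$counts), 400)
  expect_false(anyNA(cls$type))
  # multiplying all scores by k leaves labels invariant (cuts recomputed)
  cls_k <- classify_pcw(scores * 3.7)
  expect_equal(cls_k$type, cls$type)
  expect_equal(cls_k$scheme$mean, cls$scheme$mean * 3.7)
})

test_that("normal scores split into the four groups at normal-CDF shares", {
  set.seed(71)
  scores <- rnorm(10000, 800, 150)
  cls <- classify_pcw(scores)
  shares <- 100 * as.numeric(cls$counts) / 10000
  target <- 100 * c(pnorm(-1), pnorm(0) - pnorm(-1),
                    pnorm(1) - pnorm(0), pnorm(-1))
  expect_true(all(abs(shares - target) < 1.5))
})

test_that("distribution tables bin, total and accumulate correctly", {
  tab <- distribution_table(100)
  expect_equal(tab$interval[1], "(0,200]")
  expect_equal(tab$n[1], 1)
  expect_equal(tab$cumulative[nrow(tab)], 100.0)

  set.seed(81)
  scores <- runif(500, 1, 5000)
  tab <- distribution_table(scores)
  expect_equal(sum(tab$n), 500)
  expect_true(all(diff(tab$cumulative) >= 0))
  expect_equal(tab$cumulative[nrow(tab)], 100.0)
  expect_lte(abs(sum(tab$proportion) - 100), 0.1 * nrow(tab))

  expect_error(distribution_table(c(100, -5)), "-5")
  expect_error(distribution_table(0), "0")
  expect_equal(distribution_table(0, include_lowest = TRUE)$n[1], 1)
})

test_that("the fitted pcw object is internally consistent", {
  cfg <- pcw_sim_config(n = 120)
  fit <- pcw(sample_population(cfg, seed = 5))
  r <- fit$results
  expect_equal(r$pw_comm, r$pmw_comm * fit$data$t_comm)
  expect_equal(r$pcw, (r$pw_comm + r$pw_noncomm) * r$r_ov * r$r_pc * r$r_ps)
  expect_true(all(r$pcw >= 0))
  expect_equal(sum(table(r$group)), fit$n)
  expect_equal(r$ln_pcw[r$pcw > 0], log(r$pcw[r$pcw > 0]))
  # scale equivariance: doubling both times doubles every index,
  # labels invariant
  dat2 <- fit$data
  dat2$t_comm <- dat2$t_comm * 2
  dat2$t_noncomm <- dat2$t_noncomm * 2
  fit2 <- pcw(dat2)
  expect_equal(fit2$results$pcw, r$pcw * 2)
  expect_equal(fit2$results$type, r$type)
})
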