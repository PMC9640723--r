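test_that("isoform usage fractions and dominance follow the thresholds", {
  u <- compute_usage(data.frame(sample_id = c("a", "b", "c", "d"),
                                isoform_long = c(100, 0, 45, 0),
                                isoform_short = c(0, 37, 55, 0)))
  expect_equal(u$if_short, c(0, 1, 0.55, NA))
  expect_equal(u$dominance, c("long", "short", "both", "none"))
  # fractions sum to 1 whenever total > 0
  ok <- u$total > 0
  expect_equal(u$if_short[ok] + u$if_long[ok], rep(1, sum(ok)))
  # a higher both-threshold turns the 45/55 sample into a short call
  u2 <- compute_usage(data.frame(sample_id = "c", isoform_long = 45,
                                 isoform_short = 55), both_threshold = 0.5)
  expect_equal(u2$dominance, "short")
  expect_error(compute_usage(data.frame(sample_id = "x", isoform_long = -1,
                                        isoform_short = 0)), ">= 0")
})

test_that("patient exposure is any-tumor short expression and is monotone", {
  mk_usage <- function(dom) {
    data.frame(sample_id = seq_along(dom), total = 100,
               dominance = dom, stringsAsFactors = FALSE)
  }
  expect_true(exposure_by_patient(mk_usage(c("long", "short"))))
  expect_false(exposure_by_patient(mk_usage(c("long", "long", "long"))))
  # a both call counts as short expression
  expect_true(exposure_by_patient(mk_usage("both")))
  # monotone: adding a short-dominant tumor never removes exposure
  for (doms in list("long", c("long", "short"), "both")) {
    before <- exposure_by_patient(mk_usage(doms))
    after <- exposure_by_patient(mk_usage(c(doms, "short")))
    expect_true(!isTRUE(before) || isTRUE(after))
    expect_true(isTRUE(after))
  }
  zero <- data.frame(sample_id = 1, total = 0, dominance = "none")
  expect_warning(e <- exposure_by_patient(zero), "undefined")
  expect_true(is.na(e))
})

test_that("MH trend statistic matches hand computation and mantelhaen.test", {
  # hand-computed two-stratum fixture:
  # stratum 1: a=12 b=8 / c=4 d=16 -> E=8,      V=153600/62400
  # stratum 2: a=7  b=3 / c=5 d=15 -> E=4,      V=43200/26100
  # sum(a-E) = 7; statistic = (7 - 0.5)^2 / (V1 + V2)
  t1 <- matrix(c(12, 4, 8, 16), 2, 2)
  t2 <- matrix(c(7, 5, 3, 15), 2, 2)
  hand <- (7 - 0.5)^2 / (153600 / 62400 + 43200 / 26100)
  r <- mantel_haenszel_trend(list(t1, t2))
  expect_equal(r$statistic, hand, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(hand, 1, lower.tail = FALSE))
  # cross-check against the reference implementation
  arr <- array(c(t1, t2), dim = c(2, 2, 2))
  ref <- mantelhaen.test(arr, correct = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("single-stratum MH reduces to the continuity-corrected chi-square", {
  t1 <- matrix(c(10, 5, 5, 10), 2, 2)
  r <- mantel_haenszel_trend(t1)
  yates <- unname(chisq.test(t1, correct = TRUE)$statistic)
  # exact relation between the MH (N-1) and Pearson (N) variance conventions
  N <- sum(t1)
  expect_equal(r$statistic, yates * (N - 1) / N, tolerance = 1e-12)

  # identical proportions in all strata -> statistic ~ 0, p ~ 1
  flat <- matrix(c(10, 10, 20, 20), 2, 2)
  r0 <- mantel_haenszel_trend(list(flat, flat))
  expect_lt(r0$statistic, 0.05)
  expect_gt(r0$p_value, 0.8)

  expect_error(mantel_haenszel_trend(matrix(c(5, 5, 0, 0), 2, 2)),
               "degenerate")
})

test_that("isoform switch needs both the effect gate and significance", {
  # identical groups: dIF 0, no switch
  r <- detect_isoform_switch(rep(0.4, 5), rep(0.4, 5))
  expect_equal(r$dif, 0)
  expect_false(r$switch)
  # complete separation at n = 5 per group (distinct values -> exact p)
  r <- detect_isoform_switch(c(0.01, 0.02, 0.03, 0.04, 0.05),
                             c(0.90, 0.92, 0.94, 0.96, 0.98))
  expect_gt(r$dif, 0.85)
  expect_equal(r$p_value, 2 / choose(10, 5), tolerance = 1e-10)
  expect_true(r$switch)
  # significant but tiny effect fails the dIF gate
  set.seed(8)
  a <- runif(30, 0.40, 0.44); b <- runif(30, 0.46, 0.50)
  r <- detect_isoform_switch(a, b)
  expect_lt(r$p_value, 0.05)
  expect_false(r$switch)
  expect_error(detect_isoform_switch(c(0.1, 0.2), rep(0.5, 5)), ">= 3 samples")

  # BH across genes: null genes are not dragged in by one strong switch
  tab <- isoform_switch_table(list(
    SW = list(a = rep(0, 5), b = rep(1, 5)),
    NULL1 = list(a = c(0.4, 0.5, 0.6), b = c(0.4, 0.5, 0.6))))
  expect_true(tab$switch[tab$gene == "SW"])
  expect_false(tab$switch[tab$gene == "NULL1"])
  expect_true(all(tab$q_value >= tab$p_value))
})

test_that("Cox fit recovers the null and reports Wald intervals", {
  surv <- simulate_survival(sprintf("P%04d", 1:800),
                            exposure = rep(c(TRUE, FALSE), 400),
                            true_hr = 1, baseline_hazard = 0.01,
                            censor_rate = 0.2, seed = 99)
  fit <- fit_cox(surv, covariates = "exposure")
  expect_equal(nrow(fit), 1)
  expect_true(fit$ci_lower < 1 && fit$ci_upper > 1)
  expect_gt(fit$p_value, 0.01)
  expect_equal(fit$hr, exp(fit$coef))
  expect_equal(fit$ci_upper / fit$hr, exp(1.96 * fit$se), tolerance = 1e-10)
})

test_that("KM median of exponential survival converges to ln(2)/lambda", {
  lam <- 0.02
  surv <- simulate_survival(sprintf("P%05d", 1:10000),
                            exposure = rep(FALSE, 10000), true_hr = 1,
                            baseline_hazard = lam, censor_rate = 0,
                            seed = 123)
  expect_equal(sum(surv$event), 10000)  # censor_rate 0 -> all events
  km <- km_medians(surv, arm = "exposure")
  expect_equal(km$median, log(2) / lam, tolerance = 0.02)
  expect_true(km$ci_lower < km$median && km$ci_upper > km$median)
})

test_that("survival simulator validates its parameters", {
  expect_error(simulate_survival("P1", TRUE, true_hr = 0), "> 0")
  expect_error(simulate_survival("P1", TRUE, censor_rate = 1), "censor_rate")
  s <- simulate_survival(c("P1", "P2"), c(TRUE, FALSE), censor_rate = 0.5,
                         seed = 3)
  expect_true(all(s$os_months > 0))
})
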