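surv_df <- function(time, event, id = sprintf("P%02d", seq_along(time))) {
  data.frame(sample_id = id, time_months = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("median split labels the top half by density, ties by sample id", {
  expect_equal(median_split(c(a = 1, b = 2, c = 3, d = 4)),
               c(a = "low", b = "low", c = "high", d = "high"))
  # odd n: top ceiling(n/2) = 2 of 3
  expect_equal(median_split(c(a = 1, b = 2, c = 3)),
               c(a = "low", b = "high", c = "high"))
  expect_warning(lab <- median_split(c(b = 1, a = 1, d = 1, c = 1)), "tie")
  expect_equal(lab, c(b = "high", a = "high", d = "low", c = "low"))
  expect_error(median_split(c(a = 1)), "2 samples")
  expect_error(median_split(c(1, 2, 3)), "named")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # event at t=1, censored at t=2, event at t=3
  km <- km_estimate(surv_df(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
  expect_equal(km_survival_at(km, 1), 2 / 3)
  expect_equal(km_survival_at(km, 2.5), 2 / 3)
  expect_equal(km_survival_at(km, 3), 0)

  all_cens <- km_estimate(surv_df(c(2, 4, 6), rep(FALSE, 3)))
  expect_true(all(all_cens$surv == 1))

  single <- km_estimate(surv_df(5, TRUE))
  expect_equal(km_survival_at(single, 5), 0)
  expect_equal(km_survival_at(single, 4.9), 1)

  expect_error(km_estimate(surv_df(-1, TRUE)), "negative")
})

test_that("Kaplan-Meier agrees with the hand oracle under censoring", {
  set.seed(9)
  for (i in 1:10) {
    time <- round(rexp(20, 0.1), 1)
    event <- runif(20) < 0.7
    if (!any(event)) event[1] <- TRUE
    km <- km_estimate(surv_df(time, event))
    o <- oracle_km(time, event)
    expect_equal(km_survival_at(km, o$time), o$surv)
    expect_false(is.unsorted(rev(km$surv)))  # S non-increasing
  }
})

test_that("log-rank matches the hypergeometric oracle and is symmetric", {
  a <- surv_df(c(1, 2, 3), rep(TRUE, 3))
  b <- surv_df(c(4, 5, 6), rep(TRUE, 3))
  r <- logrank_test(a, b)
  o <- oracle_logrank(a$time_months, a$event, b$time_months, b$event)
  expect_equal(r$chi_square, o$chi_square)
  expect_equal(r$p_value, o$p_value)
  expect_equal(logrank_test(b, a)$chi_square, r$chi_square)

  same <- surv_df(c(1, 3, 7), c(TRUE, TRUE, FALSE))
  r0 <- logrank_test(same, same)
  expect_equal(r0$chi_square, 0)
  expect_equal(r0$p_value, 1)

  # a single event still yields a finite statistic
  one <- logrank_test(surv_df(c(2, 9), c(TRUE, FALSE)),
                      surv_df(c(5, 7), c(FALSE, FALSE)))
  expect_true(is.finite(one$chi_square))
  o1 <- oracle_logrank(c(2, 9), c(TRUE, FALSE), c(5, 7), c(FALSE, FALSE))
  expect_equal(one$chi_square, o1$chi_square)

  expect_error(logrank_test(a, surv_df(numeric(), logical())), "empty")
  expect_error(logrank_test(surv_df(1, FALSE), surv_df(2, FALSE)), "event")
})

test_that("log-rank matches the oracle on random censored datasets", {
  set.seed(14)
  for (i in 1:10) {
    a <- surv_df(round(rexp(12, 0.1), 1), runif(12) < 0.7)
    b <- surv_df(round(rexp(12, 0.2), 1), runif(12) < 0.7)
    if (!any(c(a$event, b$event))) a$event[1] <- TRUE
    r <- logrank_test(a, b)
    o <- oracle_logrank(a$time_months, a$event, b$time_months, b$event)
    expect_equal(r$chi_square, o$chi_square, tolerance = 1e-10)
  }
})

test_that("Cox estimate matches grid-search maximization of the partial likelihood", {
  # untied toy where the MLE is finite
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(TRUE, 6)
  x <- c(1, 0, 1, 0, 0, 1)
  rec <- surv_df(time, event)
  fit <- cox_univariate(rec, setNames(x, rec$sample_id))
  beta_grid <- oracle_cox_beta(time, event, x)
  expect_equal(fit$beta, beta_grid, tolerance = 2e-3)
  expect_true(fit$ci_low < fit$hazard_ratio && fit$hazard_ratio < fit$ci_high)

  set.seed(2)
  time2 <- round(rexp(15, 0.1), 2)
  x2 <- rep(c(0, 1), length.out = 15)
  rec2 <- surv_df(time2, rep(TRUE, 15))
  fit2 <- cox_univariate(rec2, setNames(x2, rec2$sample_id))
  expect_equal(fit2$beta, oracle_cox_beta(time2, rep(TRUE, 15), x2),
               tolerance = 2e-3)

  expect_error(cox_univariate(rec, setNames(rep(1, 6), rec$sample_id)),
               "constant")
  expect_error(cox_univariate(surv_df(c(1, 2), c(TRUE, FALSE)),
                              c(P01 = 0, P02 = 1)), "2 events")
})

test_that("stratified survival analysis wires KM, log-rank and Cox together", {
  set.seed(6)
  n <- 80
  x <- rep(c("high", "low"), each = n / 2)
  rate <- ifelse(x == "high", 0.03, 0.08)
  rec <- surv_df(round(rexp(n, rate), 2), rep(TRUE, n))
  strata <- setNames(x, rec$sample_id)
  res <- survival_by_stratum(rec, strata)
  expect_equal(res$levels, c("high", "low"))
  expect_named(res$km, c("high", "low"))
  # high group has the lower hazard: HR(high vs low) < 1
  expect_lt(res$cox$hazard_ratio, 1)
  expect_lt(res$logrank$p_value, 0.05)
})
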