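test_that("Breslow baseline hazard matches hand computation at beta = 0", {
  # two subjects, both events, constant covariate forces beta = 0:
  # H0(1) = 1/2 (two at risk), H0(2) = 1/2 + 1 = 3/2
  d <- tiny_dataset(time = c(1, 2), status = c(1, 1), x = c(1, 1))
  f <- suppressWarnings(fit_cox_ph(d))
  expect_equal(f$baseline_cumhaz(c(0.5, 1, 1.5, 2, 10)),
               c(0, 0.5, 0.5, 1.5, 1.5))
  tab <- f$baseline_table
  expect_equal(tab$denominator, c(2, 1))
  expect_true(all(diff(f$baseline_cumhaz(seq(0, 3, 0.1))) >= 0))
})

test_that("martingale residuals match hand computation and their range", {
  # event at t=1, censored at t=2, beta = 0: H0(1) = H0(2) = 1/2
  d <- tiny_dataset(time = c(1, 2), status = c(1, 0), x = c(5, 5))
  f <- suppressWarnings(fit_cox_ph(d))
  r <- martingale_residuals(f, d)
  expect_equal(unname(r), c(0.5, -0.5))
  expect_equal(sum(r), 0)

  # censored before the first event -> residual exactly 0
  set.seed(3)
  d2 <- tiny_dataset(time = c(5, 10, 2, 8, 7, 9), status = c(1, 1, 0, 1, 0, 1), p = 2)
  f2 <- fit_cox_ph(d2, "g01")
  expect_equal(unname(martingale_residuals(f2, d2)[3]), 0)
})

test_that("fit, baseline and residuals agree with the survival package", {
  coh <- demo_cohort()
  d <- coh$data
  f <- fit_cox_ph(d, c("G0001", "G0011", "G0002"))
  o <- survival::coxph(survival::Surv(d$time, d$status) ~
                         d$X[, f$genes], ties = "breslow")
  expect_equal(unname(f$beta), unname(coef(o)), tolerance = 1e-8)
  expect_equal(f$log_partial_likelihood, o$loglik[2], ignore_attr = TRUE)
  expect_equal(unname(martingale_residuals(f, d)),
               unname(residuals(o, type = "martingale")), tolerance = 1e-8)
  bh <- survival::basehaz(o, centered = FALSE)
  expect_equal(f$baseline_cumhaz(bh$time), bh$hazard, tolerance = 1e-8)
})

test_that("residual invariants hold across fits: r <= 1, sum zero, H0 monotone", {
  for (seed in c(1, 2, 3)) {
    coh <- demo_cohort(seed = seed, n = 120, p = 12)
    f <- fit_cox_ph(coh$data, coh$data$gene_names[1:4])
    r <- martingale_residuals(f, coh$data)
    expect_true(all(r <= 1 + 1e-12))
    expect_lt(abs(sum(r)), 1e-6 * length(r))
    grid <- seq(0, max(coh$data$time) * 1.1, length.out = 50)
    expect_true(all(diff(f$baseline_cumhaz(grid)) >= 0))
    expect_equal(f$baseline_cumhaz(0), 0)
  }
})

test_that("efron ties convention is available and sane", {
  coh <- demo_cohort(seed = 7, n = 100, p = 10)
  f <- fit_cox_ph(coh$data, coh$data$gene_names[1:3], ties = "efron")
  expect_equal(f$ties, "efron")
  expect_true(all(martingale_residuals(f, coh$data) <= 1 + 1e-12))
})

test_that("degenerate inputs are reported as errors or conventions", {
  # all censored
  d <- tiny_dataset(time = c(2, 4, 6), status = c(0, 0, 0), p = 2)
  expect_error(fit_cox_ph(d), "no events")
  # constant covariate -> beta 0 with a warning
  d2 <- tiny_dataset(time = c(1, 2, 3, 4), status = c(1, 1, 0, 1), x = rep(2, 4))
  expect_warning(f2 <- fit_cox_ph(d2), "constant")
  expect_equal(unname(f2$beta), 0)
  # monotone likelihood: covariate perfectly ordered with event time
  d3 <- tiny_dataset(time = 1:8, status = rep(1, 8), x = 8:1)
  expect_error(fit_cox_ph(d3), "converge|monotone")
  # separation guard: as many covariates as events
  d4 <- tiny_dataset(time = c(1, 2, 3, 4), status = c(1, 1, 0, 0), p = 3)
  expect_error(fit_cox_ph(d4), "too many covariates")
})

test_that("coefficients recover generator truth within 3 standard errors", {
  hits <- vapply(1:10, function(s) {
    beta <- c(G0001 = 1, G0002 = -0.5)
    coh <- generate_cohort(synthetic_spec(n = 500, p = 2, beta = beta,
                                          block_rho = 0, seed = s))
    f <- fit_cox_ph(coh$data)
    all(abs(f$beta - beta) <= 3 * f$se)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
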