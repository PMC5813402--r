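test_that("outlyingness ranking handles direction and ties", {
  Z <- cbind(m1 = c(-3, -1, 2), m2 = c(0, 0, 1))
  rownames(Z) <- c("a", "b", "c")
  R <- rank_outlyingness(Z)
  expect_equal(unname(R[, "m1"]), c(1, 2, 3))
  expect_equal(unname(R[, "m2"]), c(1.5, 1.5, 3))   # midrank under symmetry
  R_ord <- rank_outlyingness(Z, ties = "ordinal")
  expect_equal(unname(R_ord[, "m2"]), c(1, 2, 3))   # ties broken by sample order
  expect_equal(unname(rank_outlyingness(Z, direction = "descending")[, "m1"]),
               c(3, 2, 1))
  expect_equal(unname(rank_outlyingness(Z, direction = "absolute")[, "m1"]),
               c(1, 3, 2))
  # midrank columns still sum to n(n+1)/2
  expect_equal(colSums(R), c(m1 = 6, m2 = 6))
  expect_error(rank_outlyingness(cbind(c(1, NA))), "missing")
})

test_that("rank products multiply printed rank triples correctly", {
  R <- rbind(c(1, 11, 25), c(5, 2, 90), c(1, 1, 1))
  out <- rank_product(R)
  expect_equal(out$rp, c(275, 900, 1))
  expect_equal(out$log_rp, log(c(275, 900, 1)))
})

test_that("exact counting equals brute-force enumeration at small n, k", {
  for (cfg in list(c(5, 2), c(8, 2), c(5, 3), c(8, 3))) {
    n <- cfg[1]; k <- cfg[2]
    rho <- seq_len(n^k)
    expect_equal(rp_pvalue_exact(rho, n, k) * n^k, brute_rp_count(rho, n, k),
                 info = sprintf("n=%d k=%d", n, k))
  }
  # closed forms
  expect_equal(rp_pvalue_exact(3, 10, 1), 3 / 10)
  expect_equal(rp_pvalue_exact(2, 3, 2), 3 / 9)   # (1,1), (1,2), (2,1)
  expect_error(rp_pvalue_exact(10, 517, 12), "infeasible")
})

test_that("bounds bracket the exact p-value and close at the endpoints", {
  for (n in c(5, 20)) {
    for (k in 2:4) {
      grid <- unique(pmax(1, floor(exp(seq(0, k * log(n), length.out = 12)))))
      e <- rp_pvalue_exact(grid, n, k)
      b <- rp_pvalue_bounds(grid, n, k)
      expect_true(all(b$lower <= e + 1e-12), info = sprintf("n=%d k=%d", n, k))
      expect_true(all(e <= b$upper + 1e-12), info = sprintf("n=%d k=%d", n, k))
      expect_true(all(b$lower <= b$geometric_mean & b$geometric_mean <= b$upper))
    }
  }
  grid517 <- c(2, 275, 5e3, 2e5, 5e6, 1.38e8)
  e <- rp_pvalue_exact(grid517, 517, 3)
  b <- rp_pvalue_bounds(grid517, 517, 3)
  expect_true(all(b$lower <= e + 1e-12 & e <= b$upper + 1e-12))
  # interval brackets 1/3 on the tiny worked case
  b2 <- rp_pvalue_bounds(2, 3, 2)
  expect_true(b2$lower <= 1/3 && 1/3 <= b2$upper)
  # whole sample space: all three collapse to 1
  expect_equal(unlist(rp_pvalue_bounds(3^2, 3, 2)), c(lower = 1, upper = 1,
                                                      geometric_mean = 1))
})

test_that("p-values are monotone in the rank product for every method", {
  n <- 50; k <- 3
  rho <- sort(unique(floor(exp(seq(0, k * log(n), length.out = 40)))))
  expect_false(is.unsorted(rp_pvalue_exact(rho, n, k)))
  b <- rp_pvalue_bounds(rho, n, k)
  expect_false(is.unsorted(b$geometric_mean))
  expect_false(is.unsorted(rp_pvalue_gamma(log(rho), n, k)))
})

test_that("gamma approximation has its closed forms and clamps out-of-range input", {
  expect_equal(rp_pvalue_gamma(2 * log(10), 10, 2), 1)        # L = 0
  expect_equal(rp_pvalue_gamma(log(3), 10, 1), 3 / 10)        # k = 1: rho/n
  # independently computed Poisson sum e^{-L}(1 + L + L^2/2), L = 3 log 517 - log 275
  L <- 3 * log(517) - log(275)
  expect_equal(rp_pvalue_gamma(log(275), 517, 3),
               exp(-L) * (1 + L + L^2 / 2), tolerance = 1e-12)
  expect_warning(p <- rp_pvalue_gamma(-1, 10, 2), "clamp")
  expect_equal(p, rp_pvalue_gamma(0, 10, 2), ignore_attr = TRUE)
})

test_that("gamma and bounds geometric mean agree in the moderate tail", {
  # the two approximations should track each other where p is not extreme
  rho <- exp(seq(log(5e5), log(1.3e8), length.out = 20))
  g <- rp_pvalue_gamma(log(rho), 517, 3)
  bg <- rp_pvalue_bounds(rho, 517, 3)$geometric_mean
  sel <- g > 0.01
  expect_lt(max(abs(g[sel] - bg[sel]) / g[sel]), 0.05)
})

test_that("permutation p-values are reproducible, bounded and match exact", {
  R <- rbind(c(1, 1), c(2, 3), c(4, 2), c(5, 6), c(3, 3), c(6, 6))
  p1 <- rp_pvalue_permutation(R, B = 5000, seed = 12)
  p2 <- rp_pvalue_permutation(R, B = 5000, seed = 12)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 5001 & p1 <= 1))
  pe <- rp_pvalue_exact(apply(R, 1, prod), 6, 2)
  mc_se <- sqrt(pe * (1 - pe) / 5000)
  expect_true(all(abs(p1 - pe) <= 3 * pmax(mc_se, 1 / 5001)))
  expect_error(rp_pvalue_permutation(R, B = 50), "at least 100")
})

test_that("the auto dispatcher picks the method by sub-model count", {
  R3 <- generate_null_ranks(30, 3, seed = 5)
  expect_equal(unique(rp_pvalues(R3)$method), "exact")
  R6 <- generate_null_ranks(30, 6, seed = 5)
  expect_equal(unique(rp_pvalues(R6)$method), "bounds_gm")
  R100 <- generate_null_ranks(40, 100, seed = 5)
  out <- rp_pvalues(R100)
  expect_equal(unique(out$method), "gamma")
  expect_true(all(is.finite(out$p_value)) && all(out$p_value > 0))
  # explicit override is honoured and bounds columns appear
  ov <- rp_pvalues(R3, method = "bounds_gm")
  expect_equal(unique(ov$method), "bounds_gm")
  expect_true(all(c("lower", "upper") %in% names(ov)))
  expect_true(all(ov$lower <= ov$p_value & ov$p_value <= ov$upper))
})
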