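test_that("gene set union is order-preserving, idempotent, commutative, associative", {
  A <- gene_set(c("a", "b")); B <- gene_set(c("b", "c")); C <- gene_set(c("d"))
  expect_equal(as.character(union_gene_sets(list(A, B))), c("a", "b", "c"))
  expect_equal(as.character(union_gene_sets(list(A, gene_set(character(0))))),
               c("a", "b"))
  expect_length(union_gene_sets(list(gene_set(c("x", "y", "z")), gene_set(c("p", "q", "r", "s")))), 7)
  # algebraic properties on random sets, in a fixed reference order
  set.seed(1)
  pool <- paste0("g", 1:30)
  for (i in 1:20) {
    s1 <- sample(pool, 8); s2 <- sample(pool, 8); s3 <- sample(pool, 8)
    u12 <- union_gene_sets(list(s1, s2), gene_order = pool)
    expect_equal(as.character(union_gene_sets(list(u12, u12), gene_order = pool)),
                 as.character(u12))
    expect_equal(as.character(u12),
                 as.character(union_gene_sets(list(s2, s1), gene_order = pool)))
    expect_equal(
      as.character(union_gene_sets(list(u12, s3), gene_order = pool)),
      as.character(union_gene_sets(list(s1, union_gene_sets(list(s2, s3))),
                                   gene_order = pool)))
  }
  expect_equal(attr(u12, "provenance"), "union")
})

test_that("penalized selection behaves at the penalty extremes", {
  coh <- demo_cohort(seed = 10, n = 120, p = 15)
  # infinite penalty: total shrinkage, empty set but not an error
  s_inf <- select_penalized(coh$data, mixing = 1, lambda_rule = "fixed", lambda = Inf)
  expect_length(s_inf, 0)
  # near-zero penalty with p < events: everything enters
  s_0 <- select_penalized(coh$data, mixing = 1, lambda_rule = "fixed", lambda = 1e-8)
  expect_setequal(as.character(s_0), coh$data$gene_names)
  expect_equal(attr(s_inf, "provenance"), "lasso")
  expect_equal(attr(select_penalized(coh$data, mixing = 0.5, lambda_rule = "fixed",
                                     lambda = Inf), "provenance"), "elastic_net")
})

test_that("penalized selection recovers strongly planted genes", {
  hits <- vapply(1:8, function(s) {
    beta <- setNames(c(1, -1, 1), c("G0001", "G0011", "G0021"))
    coh <- generate_cohort(synthetic_spec(n = 300, p = 100, beta = beta, seed = s))
    sel <- select_penalized(coh$data, mixing = 1, seed = s)
    all(names(beta) %in% as.character(sel))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("penalized selection is reproducible given the seed", {
  coh <- demo_cohort(seed = 4, n = 150, p = 40)
  s1 <- select_penalized(coh$data, mixing = 0.5, seed = 11)
  s2 <- select_penalized(coh$data, mixing = 0.5, seed = 11)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("stepwise AIC keeps signal, mostly drops noise, and never worsens AIC", {
  kept <- dropped <- logical(0)
  for (s in 1:8) {
    coh <- generate_cohort(synthetic_spec(n = 300, p = 20,
                                          beta = c(G0001 = 1), seed = s))
    kept[s] <- "G0001" %in% as.character(stepwise_aic(coh$data, "G0001"))
    # G0015 sits in a different co-expression block: genuine noise
    dropped[s] <- length(stepwise_aic(coh$data, "G0015")) == 0L
  }
  expect_true(all(kept))
  expect_gte(mean(dropped), 0.6)  # a pure-noise gene survives only by chance

  # monotonicity: returned AIC never exceeds the starting (full) model AIC
  coh <- demo_cohort(seed = 2, n = 150, p = 12)
  cand <- coh$data$gene_names[1:8]
  res <- stepwise_aic(coh$data, cand, direction = "both")
  expect_lte(attr(res, "aic"), rpsurv:::cox_aic(coh$data, cand) + 1e-9)
  # deterministic: same call, same answer; empty candidates allowed
  expect_identical(as.character(res), as.character(stepwise_aic(coh$data, cand)))
  expect_length(stepwise_aic(coh$data, character(0)), 0)
})

test_that("stepwise errors usefully when the full model cannot be fitted", {
  d <- tiny_dataset(time = c(1, 2, 3, 4, 5), status = c(1, 1, 0, 0, 0), p = 4)
  expect_error(stepwise_aic(d, colnames(d$X)), "smaller candidate set")
})

test_that("sub-model building drops absent genes with a warning", {
  coh <- demo_cohort(seed = 5, n = 100, p = 10)
  expect_warning(
    sm <- build_submodel(coh$data, c("G0001", "G0002", "RAD51D"), "fix"),
    "RAD51D")
  expect_setequal(sm$genes, c("G0001", "G0002"))
  expect_length(sm$residuals, 100)
  expect_true(all(sm$residuals <= 1 + 1e-12))
  expect_error(build_submodel(coh$data, c("NOPE1", "NOPE2"), "bad"),
               "no listed gene")
  expect_error(build_submodel(coh$data, character(0), "empty"), "empty gene set")
})
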