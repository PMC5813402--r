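test_that("cohort generation is bitwise reproducible from its seed", {
  s <- synthetic_spec(n = 60, p = 40, seed = 123,
                      outliers = list(list(type = "long_survivor", count = 1,
                                           discrepancy_factor = 10)))
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1, c2)
  c3 <- generate_cohort(synthetic_spec(n = 60, p = 40, seed = 124))
  expect_false(identical(c1$data$X, c3$data$X))
})

test_that("achieved censoring tracks the target over seeds", {
  ach <- vapply(1:10, function(s) {
    generate_cohort(synthetic_spec(n = 517, p = 50, seed = s))$truth$achieved_censoring
  }, 0)
  expect_true(all(abs(ach - 0.45) <= 0.05))
})

test_that("planted outliers have the promised structure", {
  spec <- synthetic_spec(n = 200, p = 50, seed = 31, outliers = list(
    list(type = "long_survivor", count = 2, discrepancy_factor = 10),
    list(type = "early_death", count = 1, discrepancy_factor = 5)
  ))
  coh <- generate_cohort(spec)
  tr <- coh$truth
  expect_length(tr$outlier_ids, 3)
  expect_false(anyDuplicated(tr$outlier_ids) > 0)
  ls_ids <- tr$outlier_ids[tr$outlier_type == "long_survivor"]
  ed_ids <- tr$outlier_ids[tr$outlier_type == "early_death"]
  i_ls <- match(ls_ids, coh$data$sample_ids)
  i_ed <- match(ed_ids, coh$data$sample_ids)
  expect_true(all(coh$data$status[i_ls] == 0L))   # recorded as censored
  expect_true(all(coh$data$status[i_ed] == 1L))   # recorded as events
  # long survivors sit in the upper tail of the time distribution
  expect_true(all(coh$data$time[i_ls] >= quantile(coh$data$time, 0.9)))
})

test_that("null rank matrices are uniform permutations", {
  R <- generate_null_ranks(25, 6, seed = 2)
  expect_true(all(apply(R, 2, function(col) all(sort(unname(col)) == 1:25))))
  expect_identical(R, generate_null_ranks(25, 6, seed = 2))
  # per-cell uniformity: rank of observation 1 across many independent columns
  big <- generate_null_ranks(10, 5000, seed = 77)
  tab <- tabulate(big[1, ], nbins = 10)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("fixtures round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(synthetic_spec(n = 50, p = 20, seed = 5, outliers = list(
    list(type = "long_survivor", count = 2, discrepancy_factor = 8))))
  paths <- write_cohort_fixture(coh, dir)
  clin <- read_clinical_table(paths["clinical"])
  X <- read_expression_matrix(paths["expression"], expect_ids = clin$sample_id)
  expect_equal(rownames(X), coh$data$sample_ids)
  expect_equal(X, coh$data$X, tolerance = 1e-5)
  cleaned <- clean_clinical(clin)
  expect_setequal(cleaned$kept, coh$data$sample_ids)   # generator writes clean records
  surv <- rpsurv:::clinical_to_survival(clin)
  expect_equal(surv$time, coh$data$time, tolerance = 1e-5)
  expect_equal(surv$status, coh$data$status)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_setequal(truth$outlier_ids, coh$truth$outlier_ids)
  expect_length(truth$outlier_ids, 2)
})

test_that("a deliberately corrupted clinical fixture is caught by cleaning", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(synthetic_spec(n = 30, p = 10, n_informative = 4, seed = 6))
  paths <- write_cohort_fixture(coh, dir)
  clin <- read_clinical_table(paths["clinical"])
  bad_id <- clin$sample_id[4]
  clin$days_to_last_followup[4] <- 100
  clin$days_to_death[4] <- 107   # inconsistent day fields
  clin$vital_status[4] <- "deceased"
  out <- clean_clinical(clin)
  expect_equal(out$dropped$sample_id, bad_id)
  expect_equal(out$dropped$reason, "day_mismatch")
})
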