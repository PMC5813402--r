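test_that("clinical cleaning keeps consistent records and reasons the drops", {
  rec <- data.frame(
    sample_id = c("match", "mismatch", "dead_no_days", "alive_fup_only",
                  "dead_with_days", "no_days"),
    days_to_last_followup = c(100, 100, NA, 250, NA, NA),
    days_to_death = c(100, 90, NA, NA, 400, NA),
    vital_status = c("deceased", "deceased", "deceased", "alive", "Deceased", "alive")
  )
  out <- clean_clinical(rec)
  expect_setequal(out$kept, c("match", "alive_fup_only", "dead_with_days"))
  expect_equal(out$dropped$reason[out$dropped$sample_id == "mismatch"], "day_mismatch")
  expect_equal(out$dropped$reason[out$dropped$sample_id == "dead_no_days"],
               "deceased_missing_days")
  expect_equal(out$dropped$reason[out$dropped$sample_id == "no_days"], "no_day_fields")
})

test_that("cleaning rejects empty input and missing columns", {
  expect_error(clean_clinical(data.frame()), "no clinical records")
  expect_error(clean_clinical(data.frame(sample_id = "a")), "lacks columns")
})

test_that("cleaned records map to survival times by vital status", {
  rec <- data.frame(
    sample_id = c("a", "b"),
    days_to_last_followup = c(NA, 300),
    days_to_death = c(120, NA),
    vital_status = c("deceased", "alive")
  )
  surv <- rpsurv:::clinical_to_survival(rec)
  expect_equal(surv$time, c(120, 300))
  expect_equal(surv$status, c(1L, 0L))
})

test_that("clinical reader accepts configurable column names", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("ID\tDays to last follow-up\tDays to death\tVital status",
                     "x1\t10\t10\tdeceased",
                     "x2\t20\tNA\talive"), collapse = "\n"), f)
  tab <- read_clinical_table(f, id_col = "ID",
                             followup_col = "Days to last follow-up",
                             death_col = "Days to death",
                             status_col = "Vital status")
  expect_equal(tab$sample_id, c("x1", "x2"))
  expect_equal(tab$days_to_death, c(10, NA))
  expect_error(read_clinical_table(f), "no column")
})

test_that("expression reader auto-detects a transposed matrix", {
  d <- tiny_dataset(time = c(3, 5, 9, 11), status = c(1, 0, 1, 1), p = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  tr <- data.frame(gene = colnames(d$X), t(d$X), check.names = FALSE)
  write.table(tr, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(X <- read_expression_matrix(f, expect_ids = d$sample_ids),
                 "transposed")
  expect_equal(rownames(X), d$sample_ids)
  expect_equal(unname(X), unname(d$X))
})

test_that("gene list files ignore comments and blank lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# signature", "BRCA2", "", "PALB2  ", "CRYAB # chaperone"), f)
  expect_equal(read_gene_list(f), c("BRCA2", "PALB2", "CRYAB"))
})

test_that("survival datasets validate their invariants", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(survival_dataset(X, c(1, 2, 3, -1), c(1, 0, 1, 0)), "positive")
  expect_error(survival_dataset(X, c(1, 2, 3, NA), c(1, 0, 1, 0)), "missing")
  expect_error(survival_dataset(X, 1:4, c(1, 0, 2, 0)), "status")
  expect_error(survival_dataset(X[1, , drop = FALSE], 1, 1), "at least 2")
  expect_error(survival_dataset(X, 1:4, c(1, 0, 1, 0),
                                sample_ids = c("a", "a", "b", "c")), "unique")
})
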