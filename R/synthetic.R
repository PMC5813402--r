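#' Specify a synthetic survival cohort
#'
#' Defines the generating model for cohorts emulating a high-dimensional
#' cancer survival study: block-correlated Gaussian "expression" covariates, a
#' sparse set of informative genes acting through a proportional-hazards
#' model, independent censoring calibrated to a target rate, and optionally
#' planted influential observations whose recorded time contradicts their
#' covariate-predicted risk.
#'
#' @param n Number of samples (default 517).
#' @param p Number of genes (default 2000; raise towards 12042 for full-scale
#'   runs).
#' @param n_informative Number of genes with non-zero effect (default 16).
#'   Informative genes are spread one per co-expression block so their
#'   effects do not cancel within blocks.
#' @param beta_scale Absolute effect size of informative genes; signs
#'   alternate (default 0.25 per unit standardized expression, giving a
#'   linear-predictor standard deviation of about 1 at the defaults —
#'   hazard-ratio heterogeneity typical of a prognostic gene signature).
#' @param beta Optional explicit effect vector (length `p`, or a named
#'   vector over a subset of genes); overrides `n_informative`/`beta_scale`.
#' @param block_size,block_rho Co-expression structure: genes come in blocks
#'   of `block_size` sharing pairwise correlation `block_rho` (defaults 10
#'   and 0.4).
#' @param baseline `"exponential"` (default) or `"weibull"`.
#' @param baseline_rate Baseline hazard rate per day; the default
#'   `log(2)/923` puts the baseline median survival at 923 days.
#' @param weibull_shape Weibull shape parameter; 1 recovers the exponential.
#' @param censoring_rate Target fraction of censored samples in (0, 1)
#'   (default 0.45); exponential censoring times are calibrated to it.
#' @param outliers List of planting instructions, each a list with `type`
#'   (`"long_survivor"` or `"early_death"`), `count`, and
#'   `discrepancy_factor` (> 1). Long survivors are high-risk samples whose
#'   recorded time is multiplied by the factor and censored; early deaths are
#'   low-risk samples whose time is divided by it with an event.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n = 517L, p = 2000L, n_informative = 16L,
                           beta_scale = 0.25, beta = NULL,
                           block_size = 10L, block_rho = 0.4,
                           baseline = c("exponential", "weibull"),
                           baseline_rate = log(2) / 923, weibull_shape = 1,
                           censoring_rate = 0.45, outliers = list(), seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(n >= 2, p >= 1, block_rho >= 0, block_rho < 1,
            censoring_rate > 0, censoring_rate < 1)
  if (is.null(beta)) {
    stopifnot(n_informative <= p)
  } else {
    stopifnot(length(beta) <= p)
  }
  for (o in outliers) {
    stopifnot(o$type %in% c("long_survivor", "early_death"),
              o$count >= 1, o$count <= n, o$discrepancy_factor > 1)
  }
  structure(
    list(n = as.integer(n), p = as.integer(p),
         n_informative = as.integer(n_informative), beta_scale = beta_scale,
         beta = beta,
         block_size = as.integer(block_size), block_rho = block_rho,
         baseline = baseline, baseline_rate = baseline_rate,
         weibull_shape = weibull_shape, censoring_rate = censoring_rate,
         outliers = outliers, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic survival cohort
#'
#' Draws a cohort from a [synthetic_spec()]: expression rows from a
#' block-correlated standard Gaussian, event times from
#' \eqn{h(t) = h_0(t) \exp(\beta^\top x)}, independent exponential censoring
#' calibrated so the expected censored fraction matches the target, and then
#' plants the requested outliers by perturbing recorded times (not
#' covariates: an influential observation is a discrepant survival, not an
#' expression anomaly).
#'
#' @param spec A `"synthetic_spec"`.
#' @return A list of class `"rp_cohort"` with elements `data` (a
#'   [survival_dataset()]) and `truth` (list: `beta_true`, `outlier_ids`,
#'   `outlier_type`, `censor_times`, `achieved_censoring`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n; p <- spec$p

  # block-correlated Gaussian expression
  n_blocks <- ceiling(p / spec$block_size)
  block_id <- rep(seq_len(n_blocks), each = spec$block_size)[seq_len(p)]
  shared <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  X <- sqrt(spec$block_rho) * shared[, block_id, drop = FALSE] +
    sqrt(1 - spec$block_rho) * matrix(stats::rnorm(n * p), n, p)
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_names <- sprintf("G%04d", seq_len(p))
  dimnames(X) <- list(sample_ids, gene_names)

  beta_true <- stats::setNames(numeric(p), gene_names)
  if (!is.null(spec$beta)) {
    if (!is.null(names(spec$beta))) {
      beta_true[names(spec$beta)] <- spec$beta
    } else {
      beta_true[seq_along(spec$beta)] <- spec$beta
    }
  } else if (spec$n_informative > 0L) {
    # one informative gene per block where possible, so block correlation
    # does not cancel the signal
    if (n_blocks >= spec$n_informative) {
      idx <- 1L + (seq_len(spec$n_informative) - 1L) * spec$block_size
    } else {
      idx <- seq_len(spec$n_informative)
    }
    beta_true[idx] <- spec$beta_scale * rep_len(c(1, -1), spec$n_informative)
  }
  lp <- as.numeric(X %*% beta_true)
  theta <- spec$baseline_rate * exp(lp)   # subject-specific event rate scale

  # event times under the PH model
  u <- stats::runif(n)
  T_event <- if (spec$baseline == "exponential" || spec$weibull_shape == 1) {
    -log(u) / theta
  } else {
    (-log(u) / theta)^(1 / spec$weibull_shape)
  }

  # exponential censoring rate calibrated to the target censored fraction:
  # P(C < T) = mean_i lam / (lam + theta_i) for exponential event times
  target <- spec$censoring_rate
  cens_frac <- function(lam) mean(lam / (lam + theta))
  lam <- tryCatch(
    stats::uniroot(function(l) cens_frac(l) - target,
                   interval = c(1e-10, 1e4 * max(theta)), tol = 1e-12)$root,
    error = function(e) NA_real_
  )
  if (is.na(lam)) {
    warning(sprintf("target censoring rate %.2f unattainable; using %.2f",
                    target, cens_frac(stats::median(theta))))
    lam <- stats::median(theta)
  }
  C <- stats::rexp(n, rate = lam)
  time <- pmin(T_event, C)
  status <- as.integer(T_event <= C)

  # plant outliers by perturbing recorded time against predicted risk
  outlier_ids <- character(0)
  outlier_type <- character(0)
  used <- integer(0)
  # candidate pool: clearly high-risk (resp. low-risk) samples, i.e. the top
  # 15% of the risk score; among them, plant the ones whose recorded time is
  # already longest (resp. shortest), so that the inflated (deflated) time
  # contradicts the covariate-predicted risk as starkly as possible — a
  # high-risk patient recorded as an extreme long-term survivor
  pool_size <- max(length(spec$outliers) * 2L, ceiling(0.15 * n))
  hi_risk <- order(lp, decreasing = TRUE)[seq_len(pool_size)]
  lo_risk <- order(lp)[seq_len(pool_size)]
  for (o in spec$outliers) {
    pick <- if (o$type == "long_survivor") {
      hi_risk[order(time[hi_risk], decreasing = TRUE)]
    } else {
      lo_risk[order(time[lo_risk])]
    }
    pick <- setdiff(pick, used)[seq_len(o$count)]
    used <- c(used, pick)
    if (o$type == "long_survivor") {
      time[pick] <- time[pick] * o$discrepancy_factor
      status[pick] <- 0L
    } else {
      time[pick] <- time[pick] / o$discrepancy_factor
      status[pick] <- 1L
    }
    outlier_ids <- c(outlier_ids, sample_ids[pick])
    outlier_type <- c(outlier_type, rep(o$type, o$count))
  }

  time <- pmax(time, 1e-8)
  data <- survival_dataset(X, time, status,
                           sample_ids = sample_ids, gene_names = gene_names)
  structure(
    list(data = data,
         truth = list(beta_true = beta_true,
                      outlier_ids = outlier_ids,
                      outlier_type = outlier_type,
                      censor_times = C,
                      achieved_censoring = mean(status == 0L))),
    class = "rp_cohort"
  )
}

#' @export
print.rp_cohort <- function(x, ...) {
  print(x$data)
  cat(sprintf("  %d informative genes, %d planted outliers\n",
              sum(x$truth$beta_true != 0), length(x$truth$outlier_ids)))
  invisible(x)
}

#' Uniform random rank matrix (the analytic null)
#'
#' k independent uniform permutations of 1..n, the reference configuration of
#' the rank product null hypothesis.
#'
#' @param n,k Dimensions.
#' @param seed Integer seed.
#' @return n x k matrix; each column is a permutation of 1..n.
#' @export
generate_null_ranks <- function(n, k, seed = 1L) {
  stopifnot(n >= 1, k >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  R <- vapply(seq_len(k), function(j) sample.int(n), integer(n))
  rownames(R) <- as.character(seq_len(n))
  colnames(R) <- paste0("perm", seq_len(k))
  R
}

#' Write a cohort to plain-text fixture files
#'
#' Writes `expression.tsv` (samples x genes), `clinical.tsv` (with redundant
#' "Days to last follow-up" / "Days to death" / "Vital status" style columns
#' so the cleaning stage is exercised on re-read) and `truth.json`. The files
#' round-trip losslessly through [read_expression_matrix()] and
#' [read_clinical_table()].
#'
#' @param cohort An `"rp_cohort"` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$data
  expr_path <- file.path(dir, "expression.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  truth_path <- file.path(dir, "truth.json")

  expr <- data.frame(sample_id = d$sample_ids, d$X, check.names = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)

  dead <- d$status == 1L
  clin <- data.frame(
    sample_id = d$sample_ids,
    days_to_last_followup = ifelse(dead, NA, d$time),
    days_to_death = ifelse(dead, d$time, NA),
    vital_status = ifelse(dead, "deceased", "alive"),
    stringsAsFactors = FALSE
  )
  utils::write.table(clin, clin_path, sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(beta_true = as.list(cohort$truth$beta_true[cohort$truth$beta_true != 0]),
         outlier_ids = cohort$truth$outlier_ids,
         outlier_type = cohort$truth$outlier_type,
         achieved_censoring = cohort$truth$achieved_censoring),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(expression = expr_path, clinical = clin_path, truth = truth_path))
}
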