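#' Fit a Cox proportional hazards sub-model
#'
#' Fits a Cox model on a gene subset of a [survival_dataset()] and attaches
#' the Breslow estimate of the cumulative baseline hazard. Partial-likelihood
#' maximisation is delegated to [survival::coxph()]; the baseline hazard and
#' the martingale residuals built on top of it are computed here.
#'
#' @param data A `"survival_dataset"`.
#' @param genes Character vector of genes to include; default all genes.
#' @param ties Tie-handling convention, `"breslow"` (default; matches the
#'   plain Breslow baseline-hazard form used throughout) or `"efron"`.
#'
#' @return An object of class `"rp_coxfit"`: list with `genes`, `beta` (named
#'   coefficient vector; constant covariates get 0 with a warning), `se`
#'   (coefficient standard errors),
#'   `baseline_cumhaz` (right-continuous non-decreasing step function,
#'   0 before the first event), `baseline_table`, `log_partial_likelihood`,
#'   `n_params`, `ties`, and the `sample_ids`/`time`/`status` the fit was
#'   produced from.
#'
#' @details Covariates that are constant across samples carry no
#'   partial-likelihood information (the likelihood is flat in their
#'   coefficient); by convention their coefficient is reported as 0 with a
#'   warning. A monotone likelihood (complete separation) is reported as an
#'   error naming the offending covariates instead of returning a divergent
#'   fit. The number of covariates must stay below the number of events.
#'
#' @seealso [martingale_residuals()], [breslow_cumulative_hazard()]
#' @export
fit_cox_ph <- function(data, genes = NULL, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "survival_dataset"))
  if (is.null(genes)) genes <- data$gene_names
  genes <- as.character(genes)
  if (length(genes) < 1L) stop("at least one gene is required")
  absent <- setdiff(genes, data$gene_names)
  if (length(absent)) stop("genes absent from dataset: ", paste(absent, collapse = ", "))
  genes <- data$gene_names[data$gene_names %in% genes]  # dataset order
  d <- n_events(data)
  if (d == 0L) stop("no events: all samples are censored, the Cox model cannot be fitted")

  Xg <- data$X[, genes, drop = FALSE]
  sds <- apply(Xg, 2L, stats::sd)
  constant <- sds == 0
  if (sum(!constant) >= d) {
    stop(sprintf("too many covariates (%d) for %d events; reduce the gene set",
                 sum(!constant), d))
  }
  beta <- stats::setNames(numeric(length(genes)), genes)

  se <- stats::setNames(rep(NA_real_, length(genes)), genes)
  if (all(constant)) {
    warning("all covariates constant; returning the null model (beta = 0)")
    null_fit <- survival::coxph(survival::Surv(data$time, data$status) ~ 1,
                                ties = ties)
    loglik <- null_fit$loglik[1L]
  } else {
    if (any(constant)) {
      warning("constant covariate(s) ", paste(genes[constant], collapse = ", "),
              ": coefficient set to 0 (flat partial likelihood)")
    }
    Xfit <- Xg[, !constant, drop = FALSE]
    infinite_msg <- character(0)
    fit <- withCallingHandlers(
      survival::coxph(
        survival::Surv(data$time, data$status) ~ Xfit,
        ties = ties,
        control = survival::coxph.control(eps = 1e-9, iter.max = 100)
      ),
      warning = function(w) {
        if (grepl("infinite|did not converge", conditionMessage(w))) {
          infinite_msg <<- c(infinite_msg, conditionMessage(w))
        }
        invokeRestart("muffleWarning")
      }
    )
    cf <- stats::coef(fit)
    if (length(infinite_msg) || anyNA(cf) || any(abs(cf) > 50)) {
      bad <- genes[!constant][is.na(cf) | abs(cf) > 50]
      if (!length(bad)) bad <- genes[!constant]
      stop("Cox fit did not converge (monotone likelihood?); offending covariate(s): ",
           paste(bad, collapse = ", "))
    }
    beta[genes[!constant]] <- as.numeric(cf)
    se[genes[!constant]] <- sqrt(diag(as.matrix(fit$var)))
    loglik <- fit$loglik[2L]
  }

  out <- structure(
    list(
      genes = genes,
      beta = beta,
      se = se,
      baseline_cumhaz = NULL,
      baseline_table = NULL,
      log_partial_likelihood = loglik,
      n_params = sum(!constant),
      ties = ties,
      sample_ids = data$sample_ids,
      time = data$time,
      status = data$status
    ),
    class = "rp_coxfit"
  )
  bh <- breslow_cumulative_hazard(out, data)
  out$baseline_cumhaz <- bh
  out$baseline_table <- attr(bh, "table")
  out
}

#' @export
print.rp_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): %d genes, log partial likelihood %.3f\n",
              x$ties, length(x$genes), x$log_partial_likelihood))
  print(utils::head(x$beta, 10L))
  if (length(x$beta) > 10L) cat("...\n")
  invisible(x)
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' Computes \eqn{\hat H_0(t) = \sum_{t_j \le t} d_j / \sum_{l \in R(t_j)}
#' \exp(\hat\beta^\top x_l)} over the distinct event times \eqn{t_j} with
#' event counts \eqn{d_j} and risk sets \eqn{R(t_j)}, i.e. the Nelson-Aalen
#' estimator when \eqn{\hat\beta = 0}.
#'
#' @param fit An `"rp_coxfit"` from [fit_cox_ph()].
#' @param data The `"survival_dataset"` the fit was produced from.
#' @return A right-continuous non-decreasing step function with
#'   \eqn{\hat H_0(0) = 0}; the step table (columns `time`, `n_events`,
#'   `denominator`, `cumhaz`) is attached as attribute `"table"`.
#' @export
breslow_cumulative_hazard <- function(fit, data) {
  stopifnot(inherits(fit, "rp_coxfit"), inherits(data, "survival_dataset"))
  if (!identical(fit$sample_ids, data$sample_ids)) {
    stop("fit and data carry different samples")
  }
  lp <- as.numeric(data$X[, fit$genes, drop = FALSE] %*% fit$beta)
  risk <- exp(lp)
  ev_times <- sort(unique(data$time[data$status == 1L]))
  if (length(ev_times) == 0L) {
    f <- stats::stepfun(c(0), c(0, 0), right = FALSE)
    attr(f, "table") <- data.frame(time = numeric(0), n_events = integer(0),
                                   denominator = numeric(0), cumhaz = numeric(0))
    return(f)
  }
  d <- vapply(ev_times, function(tj) sum(data$time == tj & data$status == 1L), 0)
  denom <- vapply(ev_times, function(tj) sum(risk[data$time >= tj]), 0)
  cumhaz <- cumsum(d / denom)
  f <- stats::stepfun(ev_times, c(0, cumhaz), right = FALSE)
  attr(f, "table") <- data.frame(time = ev_times, n_events = as.integer(d),
                                 denominator = denom, cumhaz = cumhaz)
  f
}

#' Martingale residuals of a Cox sub-model
#'
#' The martingale residual of observation \eqn{i} is
#' \eqn{\hat r_i = \delta_i - \hat H_0(t_i) \exp(\hat\beta^\top x_i)}:
#' the observed minus the model-expected number of events over \eqn{(0, t_i]}.
#' Values lie in \eqn{(-\infty, 1]}; large negative values mark observations
#' that lived much longer than their covariates predict (long-term
#' survivors), values near 1 mark observations that died much earlier.
#'
#' @param fit An `"rp_coxfit"`.
#' @param data The `"survival_dataset"` the fit was produced from.
#' @return Named numeric vector of residuals, one per sample. With Breslow
#'   ties at the partial-likelihood maximum the residuals sum to zero.
#' @export
martingale_residuals <- function(fit, data) {
  stopifnot(inherits(fit, "rp_coxfit"), inherits(data, "survival_dataset"))
  if (!identical(fit$sample_ids, data$sample_ids)) {
    stop("fit and data carry different samples")
  }
  lp <- as.numeric(data$X[, fit$genes, drop = FALSE] %*% fit$beta)
  H0 <- fit$baseline_cumhaz(data$time)
  r <- data$status - H0 * exp(lp)
  names(r) <- data$sample_ids
  r
}
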