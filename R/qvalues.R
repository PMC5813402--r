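#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values: with the p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} \pi_0 \, m \, p_{(j)} / j}, clipped at 1 and
#' mapped back to the input order. `m` may exceed `length(p)` to adjust a
#' printed subset of the smallest p-values out of m tests (the unprinted
#' p-values, being larger, cannot lower any reported q).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m Total number of tests; defaults to `length(p)`.
#' @param pi0 Proportion of true nulls; fixed at 1 by default (pure
#'   Benjamini-Hochberg). An estimate may be supplied, but the default
#'   reproduces the conventional q-value exactly.
#' @return Numeric vector of q-values, same order as `p`; always
#'   `q >= p` elementwise (for `pi0 = 1`) and monotone along sorted p.
#' @export
bh_qvalues <- function(p, m = length(p), pi0 = 1) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  if (m < length(p)) stop("m must be at least length(p)")
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  o <- order(p)
  ps <- p[o]
  i <- seq_along(ps)
  q <- rev(cummin(rev(pi0 * m * ps / i)))
  q <- pmin(q, 1)
  out <- numeric(length(p))
  out[o] <- q
  out
}

#' Declare outliers at an FDR level
#'
#' @param table Data frame with columns `sample_id` and `q_value` (e.g. the
#'   result table of [rp_outliers()] or [rp_pvalues()] after [bh_qvalues()]).
#' @param alpha FDR significance level, default 0.05.
#' @return Character vector of sample ids with `q <= alpha`, sorted by
#'   ascending q.
#' @export
declare_outliers <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), all(c("sample_id", "q_value") %in% names(table)))
  hit <- table[table$q_value <= alpha, , drop = FALSE]
  hit <- hit[order(hit$q_value), , drop = FALSE]
  as.character(hit$sample_id)
}

#' Bonferroni-adjusted p-values
#'
#' Classical family-wise correction, provided for completeness; the pipeline
#' reports FDR q-values by default.
#'
#' @param p P-values in (0, 1].
#' @param m Number of tests, default `length(p)`.
#' @return Adjusted p-values `pmin(1, m * p)`.
#' @export
bonferroni_pvalues <- function(p, m = length(p)) pmin(1, m * p)
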