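#' Rank observations by outlyingness within each sub-model
#'
#' Converts an n x k outlyingness matrix (observations x sub-models; here
#' typically martingale residuals) into per-column ranks. With the default
#' ascending direction, rank 1 goes to the smallest value — for martingale
#' residuals the most negative one, i.e. the strongest long-term survivor.
#'
#' @param Z Numeric matrix, observations in rows, sub-models in columns;
#'   no missing entries. Row names are treated as sample ids.
#' @param direction `"ascending"` (default: rank 1 = smallest Z),
#'   `"descending"` (rank 1 = largest Z), or `"absolute"` (two-sided:
#'   rank 1 = largest |Z|, for symmetric "lived too long / died too soon"
#'   screens).
#' @param ties `"midrank"` (default; tied values share their average rank) or
#'   `"ordinal"` (ties broken by row order).
#' @return An n x k matrix of ranks with the dimnames of `Z`. Without ties
#'   every column is a permutation of 1..n; with midranks every column still
#'   sums to n(n+1)/2.
#' @export
rank_outlyingness <- function(Z,
                              direction = c("ascending", "descending", "absolute"),
                              ties = c("midrank", "ordinal")) {
  direction <- match.arg(direction)
  ties <- match.arg(ties)
  Z <- as.matrix(Z)
  if (!is.numeric(Z)) stop("Z must be numeric")
  if (anyNA(Z)) stop("Z contains missing entries")
  if (ncol(Z) < 1L) stop("Z needs at least one sub-model column")
  key <- switch(direction,
                ascending = Z,
                descending = -Z,
                absolute = -abs(Z))
  tm <- if (ties == "midrank") "average" else "first"
  R <- apply(key, 2L, rank, ties.method = tm)
  dimnames(R) <- dimnames(Z)
  R
}

#' Rank product of per-sub-model ranks
#'
#' \eqn{RP_i = \prod_{j=1}^k R_{ij}}; a small rank product marks an
#' observation consistently ranked as outlying across sub-models. The
#' logarithm \eqn{\sum_j \ln R_{ij}} is always computed alongside, so that
#' large numbers of sub-models cannot overflow.
#'
#' @param R Numeric matrix of ranks (observations x sub-models).
#' @return Data frame with `sample_id`, `rp` (Inf when the product overflows
#'   the double range) and `log_rp`.
#' @export
rank_product <- function(R) {
  R <- as.matrix(R)
  if (anyNA(R)) stop("rank matrix contains missing values")
  if (any(R < 1)) stop("ranks must be >= 1")
  rp <- apply(R, 1L, prod)
  log_rp <- rowSums(log(R))
  data.frame(
    sample_id = if (!is.null(rownames(R))) rownames(R) else as.character(seq_len(nrow(R))),
    rp = rp,
    log_rp = log_rp,
    stringsAsFactors = FALSE
  )
}

# ---- exact counting --------------------------------------------------------

# count of k-tuples over {1..n} with product <= m, closed forms for k <= 2
rp_count_k1 <- function(m, n) pmin(floor(m), n) * (m >= 1)

rp_count_k2 <- function(m, n) {
  m <- floor(m)
  if (m < 1) return(0)
  a <- seq_len(min(n, m))
  sum(pmin(n, m %/% a))
}

#' Exact p-value of a rank product under uniform rankings
#'
#' Computes \eqn{p = C_k(\lfloor\rho\rfloor, n) / n^k} where
#' \eqn{C_k(\rho, n)} counts the rank tuples in \eqn{\{1..n\}^k} whose
#' product does not exceed \eqn{\rho}, via the recursion
#' \eqn{C_k(\rho) = \sum_{a=1}^{\min(n,\rho)} C_{k-1}(\lfloor\rho/a\rfloor)}
#' with memoization over the distinct quotient values. Non-integer rank
#' products (midranks) are floored, a conservative choice.
#'
#' @param rho Rank product value(s), positive; vectorized.
#' @param n Number of observations (ranks run over 1..n).
#' @param k Number of sub-models.
#' @return Numeric vector of exact p-values in (0, 1].
#' @details Exact counting costs roughly \eqn{n^{k-1}} elementary operations
#'   per evaluation; for regimes beyond that budget (large k) the call errors
#'   and directs the caller to [rp_pvalue_bounds()] or [rp_pvalue_gamma()].
#' @export
rp_pvalue_exact <- function(rho, n, k) {
  stopifnot(k >= 1, n >= 1)
  if (any(rho < 1)) stop("rank products are >= 1 by construction")
  if (n^max(k - 1, 1) > 5e9) {
    stop("exact counting infeasible for n = ", n, ", k = ", k,
         "; use rp_pvalue_bounds() or rp_pvalue_gamma()")
  }
  memo <- new.env(parent = emptyenv())
  count <- function(m, kk) {
    m <- floor(m)
    if (m < 1) return(0)
    if (kk == 1L) return(rp_count_k1(m, n))
    if (m >= n^kk) return(n^kk)
    if (kk == 2L) return(rp_count_k2(m, n))
    key <- paste0(kk, ":", m)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- 0
    a <- 1
    amax <- min(n, m)
    while (a <= amax) {
      q <- m %/% a
      a2 <- min(amax, m %/% q)
      total <- total + (a2 - a + 1) * count(q, kk - 1L)
      a <- a2 + 1
    }
    memo[[key]] <- total
    total
  }
  vapply(rho, function(r) count(r, as.integer(k)) / n^k, 0)
}

# ---- recursive bounds + geometric mean -------------------------------------

#' Bounds and geometric-mean approximation of the rank product p-value
#'
#' Brackets the exact null tail probability of the rank product between a
#' rigorous lower and upper bound and reports their geometric mean as the
#' approximate p-value. The bounds come from a recursive sum-integral
#' sandwich of the counting recursion, evaluated in closed piecewise form for
#' the inner ranks, with the outermost rank summed exactly (see the methods
#' vignette for the construction). The trivial count lower bound
#' \eqn{C \ge 1} for \eqn{\rho \ge 1} is folded in so the lower bound never
#' degenerates to zero.
#'
#' @param rho Rank product value(s); vectorized.
#' @param n Number of observations.
#' @param k Number of sub-models.
#' @return Data frame with columns `lower`, `upper`, `geometric_mean`; always
#'   `lower <= exact p <= upper`.
#' @export
rp_pvalue_bounds <- function(rho, n, k) {
  stopifnot(k >= 1, n >= 1)
  if (any(rho < 1)) stop("rank products are >= 1 by construction")
  rho <- pmin(rho, n^k)
  if (k == 1L) {
    p <- rp_count_k1(rho, n) / n
    return(data.frame(lower = p, upper = p, geometric_mean = p))
  }
  lo <- numeric(length(rho))
  up <- numeric(length(rho))
  for (r in seq_len(n)) {
    x <- rho / r
    lo <- lo + rp_bound_eval(x, n, k - 1L, "lower")
    up <- up + rp_bound_eval(x, n, k - 1L, "upper")
  }
  nk <- n^k
  lo <- pmin(pmax(lo, 1), nk)   # at least the all-ones tuple
  up <- pmin(pmax(up, lo), nk)
  at_top <- rho >= nk
  lo[at_top] <- nk; up[at_top] <- nk
  data.frame(lower = lo / nk, upper = up / nk,
             geometric_mean = sqrt(lo * up) / nk)
}

# ---- gamma approximation ---------------------------------------------------

#' Gamma approximation of the rank product p-value
#'
#' Under the uniform-rankings null, \eqn{-\log(RP/n^k)} is approximately
#' Gamma(k, 1) distributed (sum of k standardized -log-uniforms), giving
#' \eqn{p \approx P(\Gamma(k,1) \ge k \log n - \log \rho)}. Operates entirely
#' on the log scale, so very large k cannot overflow. This continuous
#' approximation exceeds the discrete exact p-value in the deep tail; it is
#' the method of choice for large k where counting is infeasible.
#'
#' @param log_rho Logarithm of the rank product(s); vectorized. Values
#'   outside `[0, k log n]` are clamped with a warning.
#' @param n Number of observations.
#' @param k Number of sub-models.
#' @return Numeric vector of p-values; for `k = 1` the closed form
#'   \eqn{\rho/n} (continuous case) is recovered exactly.
#' @export
rp_pvalue_gamma <- function(log_rho, n, k) {
  stopifnot(k >= 1, n >= 1)
  top <- k * log(n)
  if (any(log_rho < 0) || any(log_rho > top + 1e-9)) {
    warning("log_rho outside [0, k log n]; clamping")
    log_rho <- pmin(pmax(log_rho, 0), top)
  }
  stats::pgamma(top - log_rho, shape = k, rate = 1, lower.tail = FALSE)
}

# ---- permutation -----------------------------------------------------------

#' Permutation p-values for observed rank products
#'
#' Monte-Carlo reference distribution under the permutation null: each draw
#' permutes every sub-model's rank column independently and takes one
#' observation's rank product (equivalently, k independent uniform ranks on
#' 1..n). Uses the add-one estimator
#' \eqn{\hat p_i = (1 + \#\{b: RP^*_b \le RP_i\})/(B+1)}, so p-values lie in
#' \eqn{[1/(B+1), 1]}.
#'
#' @param R Observed rank matrix (observations x sub-models).
#' @param B Number of null draws (at least 100).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return Numeric vector of permutation p-values, one per row of `R`.
#' @export
rp_pvalue_permutation <- function(R, B = 10000L, seed = 1L) {
  R <- as.matrix(R)
  if (B < 100L) stop("B must be at least 100")
  n <- nrow(R)
  k <- ncol(R)
  obs <- rowSums(log(R))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  null_log <- rowSums(matrix(log(sample.int(n, B * k, replace = TRUE)), B, k))
  snull <- sort(null_log)
  counts <- findInterval(obs + 1e-9, snull)
  (1 + counts) / (B + 1)
}

# ---- dispatcher ------------------------------------------------------------

#' Rank product p-values for a rank matrix
#'
#' Computes the rank product of every observation and its p-value under the
#' uniform-rankings null, dispatching on the number of sub-models k when
#' `method = "auto"`: exact counting for k <= 4, recursive bounds with
#' geometric mean for 5 <= k <= 30, and the log-domain gamma approximation
#' for k > 30.
#'
#' @param R Rank matrix (observations x sub-models), e.g. from
#'   [rank_outlyingness()] or [run_resampling()].
#' @param method `"auto"` (default), `"exact"`, `"bounds_gm"`, `"gamma"` or
#'   `"permutation"`.
#' @param B,seed Only used by the permutation method.
#' @return Data frame with `sample_id`, `rp`, `log_rp`, `p_value`, `method`,
#'   and for the bounds method also `lower` and `upper`.
#' @export
rp_pvalues <- function(R, method = c("auto", "exact", "bounds_gm", "gamma", "permutation"),
                       B = 10000L, seed = 1L) {
  method <- match.arg(method)
  R <- as.matrix(R)
  n <- nrow(R)
  k <- ncol(R)
  if (method == "auto") {
    method <- if (k <= 4L) "exact" else if (k <= 30L) "bounds_gm" else "gamma"
  }
  out <- rank_product(R)
  if (method == "exact") {
    out$p_value <- rp_pvalue_exact(out$rp, n, k)
  } else if (method == "bounds_gm") {
    b <- rp_pvalue_bounds(out$rp, n, k)
    out$p_value <- b$geometric_mean
    out$lower <- b$lower
    out$upper <- b$upper
  } else if (method == "gamma") {
    out$p_value <- rp_pvalue_gamma(out$log_rp, n, k)
  } else {
    out$p_value <- rp_pvalue_permutation(R, B = B, seed = seed)
  }
  out$method <- method
  out
}
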