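# Internal machinery for recursive bounds on the null distribution of the
# rank product.
#
# Let G_k(rho) = #{(r_1,...,r_k) in {1..n}^k : prod r_j <= rho}. G obeys
#   G_k(rho) = sum_{r=1}^{n} G_{k-1}(rho / r),   G_0(rho) = 1{rho >= 1},
# and the summand is non-increasing in r. Replacing the sum by integrals
# gives rigorous continuous envelopes, computed in closed form:
#   upper:  U_k(rho) = U_{k-1}(rho) + rho * Int_{max(1, rho/n)}^{rho} U_{k-1}(s)/s^2 ds
#   lower:  L_k(rho) =               rho * Int_{max(1, rho/(n+1))}^{rho} L_{k-1}(s)/s^2 ds
# (substitute s = rho/r; the first uses sum <= g(1) + Int_1^n g, the second
# sum >= Int_1^{n+1} g, both valid for non-increasing g >= 0). Each level is
# an exactly-integrable piecewise function of the form
#   rho * P(log rho) + Q(log rho)
# with polynomial P, Q, and breakpoints closed under multiplication by n
# (resp. n+1). The final user-facing bound additionally sums the outermost
# rank exactly (see rp_pvalue_bounds), which tightens both envelopes at no
# asymptotic cost.

# --- polynomial helpers (coefficient vectors, index j = degree j-1) -------

poly_add <- function(p, q) {
  m <- max(length(p), length(q))
  ppad <- c(p, numeric(m - length(p)))
  qpad <- c(q, numeric(m - length(q)))
  ppad + qpad
}

poly_scale <- function(p, s) p * s

# coefficients of P(x - c) expanded in powers of x
poly_shift <- function(p, c) {
  if (c == 0 || !length(p)) return(p)
  deg <- length(p) - 1L
  out <- numeric(deg + 1L)
  for (i in 0:deg) {
    pi <- p[i + 1L]
    if (pi == 0) next
    for (m in 0:i) {
      out[m + 1L] <- out[m + 1L] + pi * choose(i, m) * (-c)^(i - m)
    }
  }
  out
}

poly_eval <- function(p, x) {
  if (!length(p)) return(rep(0, length(x)))
  acc <- rep(p[length(p)], length(x))
  if (length(p) > 1L) {
    for (j in (length(p) - 1L):1L) acc <- acc * x + p[j]
  }
  acc
}

# antiderivative pieces of f(s)/s^2 for f(s) = s * A(log s) + B(log s):
#   s (log s)^j / s^2  ->  (log s)^{j+1} / (j+1)
#   (log s)^j / s^2    ->  -(1/s) * sum_{i<=j} (j!/i!) (log s)^i
# Returned as a closure evaluating the antiderivative at s > 0.
pp_antideriv_eval <- function(a, b, s) {
  ls <- log(s)
  val <- 0
  if (length(a)) {
    ia <- c(0, a / seq_along(a))      # a_j x^{j+1}/(j+1)
    val <- val + poly_eval(ia, ls)
  }
  if (length(b)) {
    deg <- length(b) - 1L
    pb <- numeric(deg + 1L)
    for (j in 0:deg) {
      bj <- b[j + 1L]
      if (bj == 0) next
      for (i in 0:j) pb[i + 1L] <- pb[i + 1L] + bj * factorial(j) / factorial(i)
    }
    val <- val - poly_eval(pb, ls) / s
  }
  val
}

# symbolic antiderivative polynomials as a function of rho for the upper
# limit s = rho (gives {a', b'} contribution to rho * A(rho)):
#   rho * (log rho)^{j+1}/(j+1)          -> a-type
#   -(rho/rho) * sum (j!/i!) (log rho)^i -> b-type (negated poly)
pp_antideriv_at_rho <- function(a, b) {
  a_out <- if (length(a)) c(0, a / seq_along(a)) else numeric(0)
  b_out <- numeric(0)
  if (length(b)) {
    deg <- length(b) - 1L
    pb <- numeric(deg + 1L)
    for (j in 0:deg) {
      bj <- b[j + 1L]
      if (bj == 0) next
      for (i in 0:j) pb[i + 1L] <- pb[i + 1L] + bj * factorial(j) / factorial(i)
    }
    b_out <- -pb
  }
  list(a = a_out, b = b_out)
}

# same for the lower limit s = rho/m (m = n or n+1): contribution to
# rho * A(rho/m), expanded in powers of log rho
pp_antideriv_at_rho_over <- function(a, b, m) {
  lm <- log(m)
  a_out <- numeric(0)
  b_out <- numeric(0)
  if (length(a)) {
    ia <- c(0, a / seq_along(a))       # polynomial in log s, s = rho/m
    a_out <- poly_shift(ia, lm)        # expand in log rho
  }
  if (length(b)) {
    deg <- length(b) - 1L
    pb <- numeric(deg + 1L)
    for (j in 0:deg) {
      bj <- b[j + 1L]
      if (bj == 0) next
      for (i in 0:j) pb[i + 1L] <- pb[i + 1L] + bj * factorial(j) / factorial(i)
    }
    # -(1/s) poly(log s) with s = rho/m: rho * (-(m/rho)) poly -> b-type
    b_out <- poly_scale(poly_shift(pb, lm), -m)
  }
  list(a = a_out, b = b_out)
}

# piecewise representation: list(breaks = c(1, ..., Inf-terminated implicitly),
# pieces = list of list(a=, b=)); piece i valid on [breaks[i], breaks[i+1]).
# The function is 0 below breaks[1] (= 1).
pp_new <- function(breaks, pieces) list(breaks = breaks, pieces = pieces)

pp_eval <- function(f, rho) {
  out <- numeric(length(rho))
  idx <- findInterval(rho, f$breaks)
  for (i in seq_along(f$pieces)) {
    sel <- idx == i
    if (!any(sel)) next
    r <- rho[sel]
    pc <- f$pieces[[i]]
    lr <- log(r)
    out[sel] <- r * poly_eval(pc$a, lr) + poly_eval(pc$b, lr)
  }
  out
}

# merge-add two piecewise functions
pp_add <- function(f, g) {
  breaks <- sort(unique(c(f$breaks, g$breaks)))
  pieces <- vector("list", length(breaks))
  mid <- function(i) {
    hi <- if (i < length(breaks)) breaks[i + 1L] else breaks[i] * 2
    sqrt(breaks[i] * hi)
  }
  for (i in seq_along(breaks)) {
    m <- mid(i)
    fi <- findInterval(m, f$breaks)
    gi <- findInterval(m, g$breaks)
    a <- numeric(0); b <- numeric(0)
    if (fi >= 1L && fi <= length(f$pieces)) {
      a <- poly_add(a, f$pieces[[fi]]$a); b <- poly_add(b, f$pieces[[fi]]$b)
    }
    if (gi >= 1L && gi <= length(g$pieces)) {
      a <- poly_add(a, g$pieces[[gi]]$a); b <- poly_add(b, g$pieces[[gi]]$b)
    }
    pieces[[i]] <- list(a = a, b = b)
  }
  pp_new(breaks, pieces)
}

# the integral transform T(F)(rho) = rho * Int_{max(1, rho/m)}^{rho} F(s)/s^2 ds
pp_transform <- function(f, m) {
  breaks <- sort(unique(c(f$breaks, f$breaks * m)))
  breaks <- breaks[is.finite(breaks)]
  pieces <- vector("list", length(breaks))
  nb <- length(breaks)
  for (i in seq_len(nb)) {
    lo <- breaks[i]
    hi <- if (i < nb) breaks[i + 1L] else lo * m
    rep_rho <- sqrt(lo * hi)

    iu <- findInterval(rep_rho, f$breaks)             # piece containing rho
    lam <- max(1, rep_rho / m)
    il <- if (lam <= 1) 1L else findInterval(lam, f$breaks)

    a <- numeric(0); b <- numeric(0)
    const <- 0

    if (iu < 1L) { pieces[[i]] <- list(a = numeric(0), b = numeric(0)); next }

    if (il == iu) {
      pc <- f$pieces[[iu]]
      up <- pp_antideriv_at_rho(pc$a, pc$b)
      a <- poly_add(a, up$a); b <- poly_add(b, up$b)
      if (rep_rho / m > 1) {
        lowr <- pp_antideriv_at_rho_over(pc$a, pc$b, m)
        a <- poly_add(a, poly_scale(lowr$a, -1)); b <- poly_add(b, poly_scale(lowr$b, -1))
      } else {
        const <- const - pp_antideriv_eval(pc$a, pc$b, 1)
      }
    } else {
      # lower fragment: from lambda (or 1) up to f$breaks[il + 1]
      pcl <- f$pieces[[il]]
      const <- const + pp_antideriv_eval(pcl$a, pcl$b, f$breaks[il + 1L])
      if (rep_rho / m > 1) {
        lowr <- pp_antideriv_at_rho_over(pcl$a, pcl$b, m)
        a <- poly_add(a, poly_scale(lowr$a, -1)); b <- poly_add(b, poly_scale(lowr$b, -1))
      } else {
        const <- const - pp_antideriv_eval(pcl$a, pcl$b, 1)
      }
      # full internal pieces
      if (iu - il >= 2L) {
        for (p in (il + 1L):(iu - 1L)) {
          pc <- f$pieces[[p]]
          const <- const +
            pp_antideriv_eval(pc$a, pc$b, f$breaks[p + 1L]) -
            pp_antideriv_eval(pc$a, pc$b, f$breaks[p])
        }
      }
      # top fragment: from f$breaks[iu] up to rho
      pcu <- f$pieces[[iu]]
      up <- pp_antideriv_at_rho(pcu$a, pcu$b)
      a <- poly_add(a, up$a); b <- poly_add(b, up$b)
      const <- const - pp_antideriv_eval(pcu$a, pcu$b, f$breaks[iu])
    }
    a <- poly_add(a, const)   # rho * const is an a-type degree-0 term
    pieces[[i]] <- list(a = a, b = b)
  }
  pp_new(breaks, pieces)
}

# base envelopes for G_1(s) = min(floor(s), n)
pp_base_upper <- function(n) {
  pp_new(c(1, n), list(list(a = 1, b = numeric(0)),     # s on [1, n)
                       list(a = numeric(0), b = n)))    # n on [n, Inf)
}
pp_base_lower <- function(n) {
  pp_new(c(1, n), list(list(a = 1, b = -1),             # s - 1 on [1, n)
                       list(a = numeric(0), b = n)))    # n on [n, Inf)
}

# build the level-k symbolic envelopes (k >= 1), cached per (n, k)
.rp_bound_cache <- new.env(parent = emptyenv())

rp_bound_envelopes <- function(n, k) {
  key <- paste0(n, ":", k)
  if (!is.null(.rp_bound_cache[[key]])) return(.rp_bound_cache[[key]])
  U <- pp_base_upper(n)
  L <- pp_base_lower(n)
  if (k >= 2L) {
    for (lev in 2:k) {
      U <- pp_add(U, pp_transform(U, n))
      L <- pp_transform(L, n + 1)
    }
  }
  env <- list(U = U, L = L)
  .rp_bound_cache[[key]] <- env
  env
}

# evaluate the level-k envelopes on a vector of rho, clamped to [0, n^k]
rp_bound_eval <- function(rho, n, k, which = c("upper", "lower")) {
  which <- match.arg(which)
  env <- rp_bound_envelopes(n, k)
  f <- if (which == "upper") env$U else env$L
  val <- pp_eval(f, rho)
  val <- pmin(pmax(val, 0), n^k)
  val[rho >= n^k] <- n^k
  val
}
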