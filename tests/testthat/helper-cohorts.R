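# Shared fixtures, all built in code at test time.

# small deterministic dataset for Cox hand checks
tiny_dataset <- function(time, status, x = NULL, p = 1) {
  n <- length(time)
  if (is.null(x)) {
    set.seed(99)
    x <- matrix(rnorm(n * p), n, p)
  }
  x <- as.matrix(x)
  dimnames(x) <- list(sprintf("s%02d", seq_len(n)), sprintf("g%02d", seq_len(ncol(x))))
  survival_dataset(x, time, status)
}

# moderate simulated cohort with known effects, shared by several files;
# the two effect genes sit in different co-expression blocks when p allows
demo_cohort <- function(seed = 42, n = 200, p = 30,
                        beta = setNames(c(1, -0.5),
                                        c("G0001", sprintf("G%04d", min(11, p))))) {
  generate_cohort(synthetic_spec(n = n, p = p, beta = beta, seed = seed))
}

# cohort with planted long-term survivors plus three disjoint gene sets that
# each carry part of the risk signature
planted_cohort <- function(seed, n = 517, p = 2000, count = 2, factor = 10,
                           set_size = 50) {
  spec <- synthetic_spec(
    n = n, p = p, seed = seed,
    outliers = list(list(type = "long_survivor", count = count,
                         discrepancy_factor = factor))
  )
  coh <- generate_cohort(spec)
  gn <- coh$data$gene_names
  inf <- gn[coh$truth$beta_true != 0]
  noise <- setdiff(gn, inf)
  set.seed(seed)
  noise_s <- sample(noise)
  nfill <- set_size - c(5, 5, 6)
  sets <- list(A = c(inf[1:5], noise_s[seq_len(nfill[1])]),
               B = c(inf[6:10], noise_s[nfill[1] + seq_len(nfill[2])]),
               C = c(inf[11:16], noise_s[nfill[1] + nfill[2] + seq_len(nfill[3])]))
  list(cohort = coh, gene_sets = sets)
}

# brute-force rank product tail count over the full tuple space
brute_rp_count <- function(rho, n, k) {
  g <- do.call(expand.grid, rep(list(seq_len(n)), k))
  prods <- apply(g, 1L, prod)
  vapply(rho, function(r) sum(prods <= r), 0)
}
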