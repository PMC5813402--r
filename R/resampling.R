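#' Configuration of the resampling consensus
#'
#' Each resampling draw picks a random gene subset without replacement, runs
#' elastic-net penalized Cox selection on it, refits an unpenalized Cox model
#' on the selected genes and ranks the martingale residuals. Repeating this
#' gives a rank matrix with one column per resampled model, which feeds the
#' rank product exactly like hand-chosen sub-models.
#'
#' @param n_genes_per_draw Genes sampled per draw (default 1000).
#' @param n_models Number of resampled models (default 100).
#' @param mixing Elastic-net mixing parameter for the per-draw selection
#'   (default 0.5).
#' @param lambda_rule,folds Penalty selection per draw (defaults `"cv_min"`,
#'   10-fold).
#' @param seed Master seed; per-draw seeds are derived from it by a
#'   counter-based scheme, so columns are reproducible independently of
#'   evaluation order.
#' @param max_redraws Redraw budget when a draw selects no genes (default 5).
#' @return A list of class `"resampling_config"`.
#' @export
resampling_config <- function(n_genes_per_draw = 1000L, n_models = 100L,
                              mixing = 0.5, lambda_rule = "cv_min",
                              folds = 10L, seed = 1L, max_redraws = 5L) {
  stopifnot(n_models >= 2, n_genes_per_draw >= 1, max_redraws >= 0)
  structure(
    list(n_genes_per_draw = as.integer(n_genes_per_draw),
         n_models = as.integer(n_models), mixing = mixing,
         lambda_rule = lambda_rule, folds = as.integer(folds),
         seed = as.integer(seed), max_redraws = as.integer(max_redraws)),
    class = "resampling_config"
  )
}

# counter-based per-draw seed, kept inside the 32-bit integer range
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 69069 + as.double(counter) * 1000003 + 12345) %%
               2147483647)
}

#' One resampling draw
#'
#' Samples `n_genes_per_draw` genes without replacement, selects among them by
#' penalized Cox regression, refits an unpenalized Cox model on the selection
#' and returns the ascending ranks of its martingale residuals (rank 1 = most
#' negative residual). Draws whose selection comes back empty are redrawn
#' with fresh genes up to `max_redraws` times (each redraw is messaged for
#' audit); exhausting the budget is an error.
#'
#' @param data A `"survival_dataset"`.
#' @param cfg A [resampling_config()].
#' @param draw_seed Integer seed for this draw (derived from the master seed
#'   by [run_resampling()]).
#' @return List with `ranks` (length-n named vector, a permutation of 1..n)
#'   and `selected_genes` (a [gene_set()] with provenance `"resample"`).
#' @export
resample_once <- function(data, cfg, draw_seed) {
  stopifnot(inherits(data, "survival_dataset"), inherits(cfg, "resampling_config"))
  m <- min(cfg$n_genes_per_draw, length(data$gene_names))
  for (attempt in 0:cfg$max_redraws) {
    seed_a <- derive_seed(draw_seed, attempt)
    set.seed(seed_a)
    pool <- sample(data$gene_names, m)
    selected <- select_penalized(data, mixing = cfg$mixing,
                                 lambda_rule = cfg$lambda_rule,
                                 folds = cfg$folds, seed = seed_a,
                                 candidates = pool)
    if (length(selected)) {
      fit <- fit_cox_ph(data, as.character(selected))
      res <- martingale_residuals(fit, data)
      ranks <- rank(res, ties.method = "first")
      return(list(ranks = ranks,
                  selected_genes = gene_set(as.character(selected), "resample")))
    }
    message("resampling draw selected no genes; redrawing (attempt ",
            attempt + 1L, "/", cfg$max_redraws, ")")
  }
  stop("resampling draw selected no genes after ", cfg$max_redraws, " redraws")
}

#' Run the resampling consensus
#'
#' Builds the n x n_models rank matrix from independent resampling draws.
#' Feed the result to [rp_pvalues()] (with `method = "auto"` large model
#' counts dispatch to the log-domain gamma approximation).
#'
#' @param data A `"survival_dataset"`.
#' @param cfg A [resampling_config()].
#' @return Rank matrix (samples x models) with the per-draw selected gene
#'   sets attached as attribute `"selected_genes"`.
#' @export
run_resampling <- function(data, cfg) {
  stopifnot(inherits(data, "survival_dataset"), inherits(cfg, "resampling_config"))
  n <- length(data$sample_ids)
  R <- matrix(NA_real_, n, cfg$n_models,
              dimnames = list(data$sample_ids, paste0("model", seq_len(cfg$n_models))))
  sets <- vector("list", cfg$n_models)
  for (j in seq_len(cfg$n_models)) {
    draw <- resample_once(data, cfg, derive_seed(cfg$seed, j))
    R[, j] <- draw$ranks
    sets[[j]] <- draw$selected_genes
  }
  attr(R, "selected_genes") <- sets
  R
}
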