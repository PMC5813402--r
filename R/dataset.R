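#' Assemble a survival dataset
#'
#' Bundles the pieces every downstream step needs: survival/censoring times in
#' days, event indicators and a samples-by-genes covariate matrix, with sample
#' and gene identifiers kept aligned throughout the pipeline.
#'
#' @param X Numeric matrix, samples in rows and genes in columns. Row and
#'   column names are used as sample and gene identifiers unless overridden.
#' @param time Positive survival or censoring time per sample, in days.
#' @param status Event indicator per sample: 1 = death observed, 0 = censored.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param gene_names Character vector of unique gene symbols.
#'
#' @return An object of class `"survival_dataset"`: a list with elements
#'   `sample_ids`, `time`, `status`, `X` and `gene_names`.
#'
#' @details Missing values anywhere in `time`, `status` or `X` are rejected
#'   rather than imputed: a silent imputation could move an observation's
#'   residual rank, which is exactly the quantity this pipeline interprets.
#'
#' @examples
#' X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), c("g1", "g2")))
#' d <- survival_dataset(X, time = rexp(10, 1 / 500) + 1, status = rbinom(10, 1, 0.6))
#' d
#' @export
survival_dataset <- function(X, time, status,
                             sample_ids = rownames(X),
                             gene_names = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(X)))
  if (is.null(gene_names)) gene_names <- paste0("gene_", seq_len(ncol(X)))
  sample_ids <- as.character(sample_ids)
  gene_names <- as.character(gene_names)
  n <- nrow(X)
  if (n < 2L) stop("a survival dataset needs at least 2 samples")
  if (length(time) != n || length(status) != n || length(sample_ids) != n) {
    stop("time, status and sample_ids must have one entry per row of X")
  }
  if (length(gene_names) != ncol(X)) stop("gene_names must match ncol(X)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  if (anyNA(time) || anyNA(status) || anyNA(X)) {
    stop("missing values in time, status or X are not allowed (not imputed)")
  }
  time <- as.numeric(time)
  status <- as.integer(status)
  if (any(time <= 0)) stop("all times must be positive")
  if (!all(status %in% c(0L, 1L))) stop("status must be 0 (censored) or 1 (event)")
  dimnames(X) <- list(sample_ids, gene_names)
  structure(
    list(sample_ids = sample_ids, time = time, status = status,
         X = X, gene_names = gene_names),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "Survival dataset: %d samples x %d genes, %d events (%.1f%% censored)\n",
    length(x$sample_ids), length(x$gene_names), sum(x$status),
    100 * mean(x$status == 0L)
  ))
  cat(sprintf("  time range: %.0f - %.0f days\n", min(x$time), max(x$time)))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) dim(x$X)

n_events <- function(data) sum(data$status == 1L)

# Restrict to a gene subset, preserving dataset gene order.
subset_genes <- function(data, genes) {
  genes <- intersect(data$gene_names, genes)
  survival_dataset(data$X[, genes, drop = FALSE], data$time, data$status,
                   sample_ids = data$sample_ids, gene_names = genes)
}
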