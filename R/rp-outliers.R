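#' Rank product consensus test for influential observations
#'
#' The core analysis: fit several Cox proportional hazards sub-models to the
#' same cohort, rank every observation's martingale residual within each
#' sub-model, combine the ranks with the rank product statistic, and assess
#' each observation against the uniform-rankings null, with FDR control over
#' the n per-observation tests. Observations consistently ranked as outlying
#' — long-term survivors with the default ascending direction — get small
#' rank products and small q-values, regardless of which single sub-model one
#' would have trusted.
#'
#' @param data A [survival_dataset()].
#' @param gene_sets Named list of gene vectors (or [gene_set()]s); one Cox
#'   sub-model is fitted per entry. Alternatively supply `submodels` or
#'   `scores`.
#' @param submodels List of prebuilt `"rp_submodel"` objects (see
#'   [build_submodel()]).
#' @param scores Optional n x k matrix of externally supplied outlyingness
#'   scores (e.g. robust-Cox weights); bypasses the internal Cox fits and is
#'   ranked directly.
#' @param rank_matrix Optional n x k rank matrix (e.g. from
#'   [run_resampling()]); used as-is.
#' @param direction,ties Passed to [rank_outlyingness()]; defaults ascending
#'   / midrank (rank 1 = most negative martingale residual).
#' @param method P-value method, see [rp_pvalues()]; default `"auto"`.
#' @param alpha FDR level for the outlier call (default 0.05).
#' @param pi0 Null proportion for [bh_qvalues()] (default 1).
#' @param B,seed Permutation-method parameters.
#' @param ties_cox Tie convention for the Cox fits.
#'
#' @return An object of class `"rp_outliers"`: list with
#'   \describe{
#'     \item{table}{data frame (one row per observation, sorted by q
#'       ascending): `sample_id`, `time`, `status`, one `rank_<label>` column
#'       per sub-model, `rp`, `log_rp`, `p_value`, `q_value`, `outlier`.}
#'     \item{submodels}{the fitted sub-models (when built here).}
#'     \item{residual_matrix}{n x k matrix of martingale residuals (when
#'       available).}
#'     \item{alpha, method, n, k, call}{bookkeeping.}
#'   }
#'
#' @examples
#' coh <- generate_cohort(synthetic_spec(n = 120, p = 60, n_informative = 6,
#'   outliers = list(list(type = "long_survivor", count = 2,
#'                        discrepancy_factor = 10)), seed = 7))
#' sets <- list(A = paste0("G", sprintf("%04d", 1:20)),
#'              B = paste0("G", sprintf("%04d", 21:40)),
#'              C = paste0("G", sprintf("%04d", c(1:5, 41:55))))
#' fit <- rp_outliers(coh$data, gene_sets = sets)
#' fit
#' outliers(fit)
#' @export
rp_outliers <- function(data, gene_sets = NULL, submodels = NULL, scores = NULL,
                        rank_matrix = NULL,
                        direction = c("ascending", "descending", "absolute"),
                        ties = c("midrank", "ordinal"),
                        method = c("auto", "exact", "bounds_gm", "gamma", "permutation"),
                        alpha = 0.05, pi0 = 1, B = 10000L, seed = 1L,
                        ties_cox = "breslow") {
  direction <- match.arg(direction)
  ties <- match.arg(ties)
  method <- match.arg(method)
  stopifnot(inherits(data, "survival_dataset"))
  sources <- !vapply(list(gene_sets, submodels, scores, rank_matrix), is.null, TRUE)
  if (sum(sources) != 1L) {
    stop("supply exactly one of gene_sets, submodels, scores or rank_matrix")
  }

  Z <- NULL
  fits <- NULL
  if (!is.null(gene_sets)) {
    if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
      names(gene_sets) <- paste0("m", seq_along(gene_sets))
    }
    fits <- Map(function(g, lab) build_submodel(data, g, lab, ties = ties_cox),
                gene_sets, names(gene_sets))
  } else if (!is.null(submodels)) {
    stopifnot(all(vapply(submodels, inherits, TRUE, "rp_submodel")))
    fits <- submodels
  }
  if (!is.null(fits)) {
    Z <- vapply(fits, function(s) s$residuals, numeric(length(data$sample_ids)))
    rownames(Z) <- data$sample_ids
    colnames(Z) <- vapply(fits, `[[`, "", "label")
  } else if (!is.null(scores)) {
    Z <- as.matrix(scores)
    if (nrow(Z) != length(data$sample_ids)) stop("scores must have one row per sample")
    if (is.null(rownames(Z))) rownames(Z) <- data$sample_ids
    if (is.null(colnames(Z))) colnames(Z) <- paste0("m", seq_len(ncol(Z)))
  }

  R <- if (!is.null(Z)) rank_outlyingness(Z, direction, ties) else {
    Rm <- as.matrix(rank_matrix)
    if (nrow(Rm) != length(data$sample_ids)) {
      stop("rank_matrix must have one row per sample")
    }
    if (is.null(rownames(Rm))) rownames(Rm) <- data$sample_ids
    Rm
  }

  res <- rp_pvalues(R, method = method, B = B, seed = seed)
  res$q_value <- bh_qvalues(res$p_value, m = nrow(R), pi0 = pi0)

  tab <- data.frame(sample_id = data$sample_ids,
                    time = data$time, status = data$status,
                    stringsAsFactors = FALSE)
  ranks_df <- as.data.frame(R)
  names(ranks_df) <- paste0("rank_", colnames(R))
  tab <- cbind(tab, ranks_df)
  tab <- merge(tab, res[, setdiff(names(res), "method")], by = "sample_id", sort = FALSE)
  tab$outlier <- tab$q_value <= alpha
  tab <- tab[order(tab$q_value, tab$rp), , drop = FALSE]
  rownames(tab) <- NULL

  structure(
    list(table = tab, submodels = fits, residual_matrix = Z, rank_matrix = R,
         alpha = alpha, method = res$method[1L], direction = direction,
         n = nrow(R), k = ncol(R), call = match.call()),
    class = "rp_outliers"
  )
}

#' Extract the declared outliers
#'
#' @param x An `"rp_outliers"` object.
#' @param alpha FDR level; defaults to the level stored in the fit.
#' @return Character vector of sample ids with `q <= alpha`, ascending in q.
#' @export
outliers <- function(x, alpha = x$alpha) {
  stopifnot(inherits(x, "rp_outliers"))
  declare_outliers(x$table, alpha)
}

#' @export
print.rp_outliers <- function(x, ...) {
  cat(sprintf(
    "Rank product consensus over %d sub-models, %d observations (method: %s)\n",
    x$k, x$n, x$method))
  out <- outliers(x)
  cat(sprintf("Outliers at q <= %.3g: %s\n", x$alpha,
              if (length(out)) paste(out, collapse = ", ") else "none"))
  cat("\nTop of the consensus table:\n")
  print(utils::head(format_rp_table(x$table), 5L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.rp_outliers <- function(object, ...) {
  structure(
    list(n = object$n, k = object$k, method = object$method,
         alpha = object$alpha, outliers = outliers(object),
         table = object$table,
         submodel_sizes = if (!is.null(object$submodels)) {
           vapply(object$submodels, function(s) length(s$genes), 0L)
         }),
    class = "summary.rp_outliers"
  )
}

#' @export
print.summary.rp_outliers <- function(x, ...) {
  cat(sprintf("Rank product consensus: n = %d observations, k = %d sub-models\n",
              x$n, x$k))
  if (!is.null(x$submodel_sizes)) {
    cat("Sub-model sizes:",
        paste(sprintf("%s=%d", names(x$submodel_sizes), x$submodel_sizes),
              collapse = ", "), "\n")
  }
  cat(sprintf("P-value method: %s; FDR level: %.3g\n", x$method, x$alpha))
  cat(sprintf("%d outlier(s): %s\n", length(x$outliers),
              if (length(x$outliers)) paste(x$outliers, collapse = ", ") else ""))
  cat("\n")
  print(utils::head(format_rp_table(x$table), 10L), row.names = FALSE)
  invisible(x)
}

#' @export
residuals.rp_outliers <- function(object, ...) {
  if (is.null(object$residual_matrix)) {
    stop("no residual matrix available (fit was built from a rank matrix)")
  }
  object$residual_matrix
}

#' @export
as.data.frame.rp_outliers <- function(x, ...) x$table

#' Plot martingale residuals per sub-model
#'
#' Residual-versus-index scatter for each sub-model with declared outliers
#' highlighted — the standard visual check that flagged observations are the
#' ones sitting far below the residual cloud.
#'
#' @param x An `"rp_outliers"` object carrying residuals.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rp_outliers <- function(x, ...) {
  Z <- residuals.rp_outliers(x)
  k <- ncol(Z)
  out_ids <- outliers(x)
  old <- graphics::par(mfrow = c(1, k), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_len(k)) {
    col <- ifelse(rownames(Z) %in% out_ids, "red", "grey40")
    graphics::plot(seq_len(nrow(Z)), Z[, j], col = col,
                   pch = ifelse(rownames(Z) %in% out_ids, 19, 1),
                   xlab = "observation index", ylab = "martingale residual",
                   main = colnames(Z)[j], ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

# p-values in scientific notation (3 significant digits), q-values with 4
# decimals, mirroring the conventional reporting format
format_rp_table <- function(tab) {
  out <- tab
  out$p_value <- sprintf("%.2E", tab$p_value)
  out$q_value <- sprintf("%.4f", tab$q_value)
  if ("rp" %in% names(out)) out$rp <- format(tab$rp, digits = 6)
  if ("log_rp" %in% names(out)) out$log_rp <- sprintf("%.3f", tab$log_rp)
  for (cl in c("lower", "upper")) {
    if (cl %in% names(out)) out[[cl]] <- sprintf("%.2E", tab[[cl]])
  }
  out
}
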