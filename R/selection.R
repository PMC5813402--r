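#' Construct a gene set
#'
#' A gene set is an ordered character vector of unique gene symbols with a
#' provenance tag recording how it was obtained.
#'
#' @param names Character vector of gene symbols (duplicates removed, first
#'   occurrence kept).
#' @param provenance One of `"lasso"`, `"elastic_net"`, `"union"`,
#'   `"stepwise_aic"`, `"fixed_list"`, `"resample"`.
#' @return Character vector of class `"gene_set"` with attribute `provenance`.
#' @export
gene_set <- function(names,
                     provenance = c("fixed_list", "lasso", "elastic_net",
                                    "union", "stepwise_aic", "resample")) {
  provenance <- match.arg(provenance)
  names <- unique(as.character(names))
  structure(names, provenance = provenance, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set (%s): %d genes\n", attr(x, "provenance"), length(x)))
  if (length(x)) cat(" ", paste(utils::head(unclass(x), 12L), collapse = ", "),
                     if (length(x) > 12L) "..." else "", "\n")
  invisible(x)
}

#' Penalized Cox gene selection
#'
#' Runs a lasso (`mixing = 1`) or elastic-net (`0 < mixing < 1`) penalized Cox
#' regression and returns the genes with non-zero coefficient at the selected
#' penalty strength. Path numerics are delegated to [glmnet::glmnet()];
#' covariates are standardized internally by glmnet and coefficients relate to
#' the original scale.
#'
#' @param data A `"survival_dataset"`.
#' @param mixing Elastic-net mixing parameter in (0, 1]; 1 = lasso, 0.5 is the
#'   conventional default when "elastic net" is requested without a value.
#' @param lambda_rule `"cv_min"` (default; cross-validated minimum),
#'   `"cv_1se"`, or `"fixed"` (then `lambda` must be given).
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param lambda Penalty strength when `lambda_rule = "fixed"`.
#' @param candidates Optional gene subset to select from; default all genes.
#' @return A [gene_set()] with provenance `"lasso"` or `"elastic_net"`. An
#'   empty set (total shrinkage) is a legitimate result, not an error.
#' @export
select_penalized <- function(data, mixing = 1,
                             lambda_rule = c("cv_min", "cv_1se", "fixed"),
                             folds = 10L, seed = 1L, lambda = NULL,
                             candidates = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(inherits(data, "survival_dataset"), mixing > 0, mixing <= 1)
  if (n_events(data) == 0L) stop("no events: penalized selection impossible")
  if (is.null(candidates)) candidates <- data$gene_names
  candidates <- data$gene_names[data$gene_names %in% candidates]
  X <- data$X[, candidates, drop = FALSE]
  y <- survival::Surv(data$time, data$status)
  provenance <- if (mixing == 1) "lasso" else "elastic_net"

  if (lambda_rule == "fixed") {
    if (is.null(lambda)) stop("lambda_rule = 'fixed' requires lambda")
    if (!is.finite(lambda)) return(gene_set(character(0), provenance))
    fit <- glmnet::glmnet(X, y, family = "cox", alpha = mixing, standardize = TRUE)
    cf <- stats::coef(fit, s = lambda, exact = FALSE)
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    foldid <- sample(rep_len(seq_len(folds), nrow(X)))
    cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = mixing,
                            foldid = foldid, standardize = TRUE)
    s <- if (lambda_rule == "cv_min") cv$lambda.min else cv$lambda.1se
    cf <- stats::coef(cv, s = s)
  }
  nz <- rownames(cf)[as.numeric(cf) != 0]
  gene_set(nz, provenance)
}

#' Union of gene sets
#'
#' Set-theoretic union, returned in a reference gene order so that all
#' sub-models downstream share a consistent covariate ordering. Idempotent,
#' commutative and associative.
#'
#' @param sets List of [gene_set()]s (or plain character vectors).
#' @param gene_order Optional character vector (typically the dataset's
#'   `gene_names`) fixing the output order; default: first-seen order.
#' @return A [gene_set()] with provenance `"union"`.
#' @export
union_gene_sets <- function(sets, gene_order = NULL) {
  stopifnot(is.list(sets))
  all_genes <- unique(unlist(lapply(sets, as.character), use.names = FALSE))
  if (!is.null(gene_order)) {
    outside <- setdiff(all_genes, gene_order)
    if (length(outside)) stop("genes not in gene_order: ", paste(outside, collapse = ", "))
    all_genes <- gene_order[gene_order %in% all_genes]
  }
  gene_set(all_genes, "union")
}

# AIC of a Cox sub-model: -2 log partial likelihood + 2 #covariates.
# The empty model uses the null partial likelihood.
cox_aic <- function(data, genes, ties = "breslow") {
  if (length(genes) == 0L) {
    null_fit <- survival::coxph(survival::Surv(data$time, data$status) ~ 1, ties = ties)
    return(-2 * null_fit$loglik[1L])
  }
  fit <- suppressWarnings(fit_cox_ph(data, genes, ties = ties))
  -2 * fit$log_partial_likelihood + 2 * fit$n_params
}

#' Stepwise AIC gene selection for the Cox model
#'
#' Greedy single-gene add/drop search minimizing
#' \eqn{AIC = -2 \log PL + 2 \times \#genes}, terminating when no single move
#' improves the AIC. Deterministic given the data and candidate order: ties
#' are broken in favour of the earlier candidate.
#'
#' @param data A `"survival_dataset"`.
#' @param candidates Candidate genes (a [gene_set()] or character vector).
#'   An empty candidate set returns an empty set.
#' @param direction `"both"` (default, starting from the full candidate
#'   model), `"backward"`, or `"forward"` (starting from the empty model).
#' @param ties Tie convention passed to the Cox fits.
#' @param max_steps Safety cap on the number of greedy moves.
#' @return A [gene_set()] with provenance `"stepwise_aic"`; the achieved AIC
#'   is attached as attribute `"aic"`, never above the starting model's AIC.
#' @export
stepwise_aic <- function(data, candidates,
                         direction = c("both", "backward", "forward"),
                         ties = "breslow", max_steps = 200L) {
  direction <- match.arg(direction)
  stopifnot(inherits(data, "survival_dataset"))
  candidates <- as.character(candidates)
  candidates <- data$gene_names[data$gene_names %in% candidates]
  if (length(candidates) == 0L) {
    out <- gene_set(character(0), "stepwise_aic")
    attr(out, "aic") <- cox_aic(data, character(0), ties)
    return(out)
  }
  current <- if (direction == "forward") character(0) else candidates
  if (direction != "forward") {
    # the full model must be fittable to anchor the search
    aic_now <- tryCatch(cox_aic(data, current, ties), error = function(e) {
      stop("full candidate model unfittable (", conditionMessage(e),
           "); supply a smaller candidate set")
    })
  } else {
    aic_now <- cox_aic(data, current, ties)
  }

  can_add <- direction %in% c("forward", "both")
  can_drop <- direction %in% c("backward", "both")
  for (step in seq_len(max_steps)) {
    moves <- list()
    if (can_drop && length(current)) {
      for (g in current) moves[[length(moves) + 1L]] <- list(op = "drop", gene = g)
    }
    if (can_add) {
      for (g in setdiff(candidates, current)) {
        moves[[length(moves) + 1L]] <- list(op = "add", gene = g)
      }
    }
    if (!length(moves)) break
    aics <- vapply(moves, function(m) {
      genes <- if (m$op == "drop") setdiff(current, m$gene) else c(current, m$gene)
      genes <- candidates[candidates %in% genes]
      tryCatch(cox_aic(data, genes, ties), error = function(e) Inf)
    }, 0)
    best <- which.min(aics)  # earliest candidate wins ties
    if (aics[best] >= aic_now - 1e-10) break
    m <- moves[[best]]
    current <- if (m$op == "drop") setdiff(current, m$gene) else c(current, m$gene)
    current <- candidates[candidates %in% current]
    aic_now <- aics[best]
  }
  out <- gene_set(current, "stepwise_aic")
  attr(out, "aic") <- aic_now
  out
}

#' Build a sub-model: Cox fit plus martingale residuals
#'
#' Fits a Cox model on the given genes and attaches the martingale residuals
#' that feed the rank product. Genes absent from the expression matrix are
#' dropped with a warning (mirroring the handling of list genes missing from
#' a cohort's platform); if none remain the call errors.
#'
#' @param data A `"survival_dataset"`.
#' @param genes A [gene_set()] or character vector.
#' @param label Short label identifying the sub-model in result tables.
#' @param ties Tie convention for the Cox fit.
#' @return An object of class `"rp_submodel"`: list with `label`, `genes`,
#'   `fit` (an `"rp_coxfit"`) and `residuals` (length-n named vector).
#' @export
build_submodel <- function(data, genes, label, ties = "breslow") {
  stopifnot(inherits(data, "survival_dataset"))
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene set for sub-model '", label, "'")
  present <- genes[genes %in% data$gene_names]
  absent <- setdiff(genes, present)
  if (!length(present)) stop("sub-model '", label, "': no listed gene present in the data")
  if (length(absent)) {
    warning("sub-model '", label, "': dropping gene(s) absent from the data: ",
            paste(absent, collapse = ", "))
  }
  fit <- fit_cox_ph(data, present, ties = ties)
  structure(
    list(label = as.character(label), genes = fit$genes, fit = fit,
         residuals = martingale_residuals(fit, data)),
    class = "rp_submodel"
  )
}

#' @export
print.rp_submodel <- function(x, ...) {
  cat(sprintf("Sub-model '%s': %d genes, residual range [%.3f, %.3f]\n",
              x$label, length(x$genes), min(x$residuals), max(x$residuals)))
  invisible(x)
}
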