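#' Load and validate an analysis configuration
#'
#' The pipeline is driven by a small configuration (YAML file or R list):
#'
#' ```yaml
#' expression: expression.tsv
#' clinical: clinical.tsv
#' alpha: 0.05
#' rp_method: auto
#' direction: ascending
#' tie_method: midrank
#' seed: 1
#' submodels:
#'   - {label: listA, source: fixed_list, genes_file: listA.txt}
#'   - {label: lasso, source: lasso}
#'   - {label: enet63, source: union_stepwise, mixing: 0.5}
#' resampling: {n_models: 20, n_genes_per_draw: 300}
#' ```
#'
#' Sub-model sources: `fixed_list` (genes from `genes_file` or inline
#' `genes`), `lasso`, `elastic_net` (optional `mixing`, default 0.5), and
#' `union_stepwise` (lasso and elastic-net selections, union, then stepwise
#' AIC reduction — the construction used for a "selected then reduced"
#' sub-model).
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated config list of class `"analysis_config"`.
#' @export
analysis_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  defaults <- list(alpha = 0.05, rp_method = "auto", direction = "ascending",
                   tie_method = "midrank", seed = 1L, pi0 = 1,
                   clinical_columns = list())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config[["expression"]])) stop("config: 'expression' path is required")
  if (is.null(config[["clinical"]])) stop("config: 'clinical' path is required")
  has_sub <- length(config$submodels) > 0L
  has_res <- !is.null(config$resampling)
  if (!has_sub && !has_res) {
    stop("config: at least one sub-model or a resampling block is required")
  }
  for (sm in config$submodels) {
    if (is.null(sm$label)) stop("config: every submodel needs a label")
    if (is.null(sm$source) ||
        !sm$source %in% c("fixed_list", "lasso", "elastic_net", "union_stepwise")) {
      stop("config: submodel '", sm$label, "' has unknown source '",
           sm$source, "'")
    }
    if (sm$source == "fixed_list" && is.null(sm$genes_file) && is.null(sm$genes)) {
      stop("config: fixed_list submodel '", sm$label,
           "' needs 'genes_file' or 'genes'")
    }
  }
  structure(config, class = c("analysis_config", "list"))
}

build_configured_geneset <- function(data, sm, seed) {
  switch(sm$source,
    fixed_list = {
      genes <- if (!is.null(sm$genes_file)) read_gene_list(sm$genes_file)
               else as.character(sm$genes)
      gene_set(genes, "fixed_list")
    },
    lasso = select_penalized(data, mixing = 1,
                             lambda_rule = sm$lambda_rule %||% "cv_min",
                             folds = sm$folds %||% 10L, seed = seed),
    elastic_net = select_penalized(data, mixing = sm$mixing %||% 0.5,
                                   lambda_rule = sm$lambda_rule %||% "cv_min",
                                   folds = sm$folds %||% 10L, seed = seed),
    union_stepwise = {
      s1 <- select_penalized(data, mixing = 1,
                             lambda_rule = sm$lambda_rule %||% "cv_min",
                             folds = sm$folds %||% 10L, seed = seed)
      s2 <- select_penalized(data, mixing = sm$mixing %||% 0.5,
                             lambda_rule = sm$lambda_rule %||% "cv_min",
                             folds = sm$folds %||% 10L, seed = seed + 1L)
      u <- union_gene_sets(list(s1, s2), gene_order = data$gene_names)
      if (!length(u)) stop("submodel '", sm$label, "': empty union selection")
      stepwise_aic(data, u, direction = sm$stepwise_direction %||% "both")
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full outlier analysis pipeline
#'
#' Reads expression and clinical tables, cleans the clinical records, builds
#' the configured sub-models, computes martingale-residual ranks, rank
#' products, p-values and q-values, writes the report files and returns the
#' fitted [rp_outliers()] object.
#'
#' Output files under `out_dir`: `consensus.tsv` (ID, time, status,
#' per-sub-model ranks, RP, p-value, q-value, sorted by q), `outliers.tsv`,
#' one `residuals_<label>.tsv` per sub-model, optionally `resampling.tsv`
#' (ID, per-model ranks, p, q), and `run_log.txt` (config echo, seeds,
#' package version, dropped clinical records with reasons).
#'
#' @param config An [analysis_config()], YAML path or list.
#' @param out_dir Output directory; defaults to `config$output_dir`.
#' @return Invisibly, a list with the `"rp_outliers"` fit, the resampling
#'   table (or NULL) and the vector of written file paths.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  cfg <- analysis_config(config)
  out_dir <- out_dir %||% cfg$output_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cc <- cfg$clinical_columns
  clin_raw <- read_clinical_table(
    cfg[["clinical"]],
    id_col = cc$id %||% "sample_id",
    followup_col = cc$followup %||% "days_to_last_followup",
    death_col = cc$death %||% "days_to_death",
    status_col = cc$status %||% "vital_status",
    sep = cc$sep %||% "\t"
  )
  X <- read_expression_matrix(cfg[["expression"]], expect_ids = clin_raw$sample_id)

  offenders <- c(setdiff(rownames(X), clin_raw$sample_id),
                 setdiff(clin_raw$sample_id, rownames(X)))
  if (length(offenders)) {
    stop("sample-ID mismatch between expression and clinical tables: ",
         paste(utils::head(offenders, 20L), collapse = ", "),
         if (length(offenders) > 20L) " ..." else "")
  }

  cleaned <- clean_clinical(clin_raw)
  surv <- clinical_to_survival(clin_raw[clin_raw$sample_id %in% cleaned$kept, ])
  surv <- surv[match(intersect(rownames(X), surv$sample_id), surv$sample_id), ]
  data <- survival_dataset(X[surv$sample_id, , drop = FALSE],
                           surv$time, surv$status,
                           sample_ids = surv$sample_id)

  files <- character(0)
  fit <- NULL
  if (length(cfg$submodels)) {
    gene_sets <- list()
    for (sm in cfg$submodels) {
      gene_sets[[sm$label]] <- build_configured_geneset(data, sm, as.integer(cfg$seed))
    }
    fit <- rp_outliers(data, gene_sets = gene_sets,
                       direction = cfg$direction, ties = cfg$tie_method,
                       method = cfg$rp_method, alpha = cfg$alpha,
                       pi0 = cfg$pi0, seed = as.integer(cfg$seed))
    cons_path <- file.path(out_dir, "consensus.tsv")
    utils::write.table(format_rp_table(fit$table), cons_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, consensus = cons_path)

    out_path <- file.path(out_dir, "outliers.tsv")
    utils::write.table(
      fit$table[fit$table$outlier, c("sample_id", "time", "status", "rp",
                                     "p_value", "q_value")],
      out_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, outliers = out_path)

    for (s in fit$submodels) {
      rp_ranks <- fit$table[match(data$sample_ids, fit$table$sample_id),
                            paste0("rank_", s$label)]
      sm_tab <- data.frame(sample_id = data$sample_ids,
                           residual = s$residuals, rank = rp_ranks)
      sm_path <- file.path(out_dir, paste0("residuals_", s$label, ".tsv"))
      utils::write.table(sm_tab, sm_path, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, sm_path)
    }
  }

  res_tab <- NULL
  if (!is.null(cfg$resampling)) {
    rs <- cfg$resampling
    rcfg <- resampling_config(
      n_genes_per_draw = rs$n_genes_per_draw %||% 1000L,
      n_models = rs$n_models %||% 100L,
      mixing = rs$mixing %||% 0.5,
      lambda_rule = rs$lambda_rule %||% "cv_min",
      folds = rs$folds %||% 10L,
      seed = as.integer(rs$seed %||% cfg$seed),
      max_redraws = rs$max_redraws %||% 5L
    )
    R <- run_resampling(data, rcfg)
    pv <- rp_pvalues(R, method = "auto")
    pv$q_value <- bh_qvalues(pv$p_value, m = nrow(R), pi0 = cfg$pi0)
    res_tab <- cbind(data.frame(sample_id = rownames(R)), as.data.frame(R),
                     p_value = pv$p_value[match(rownames(R), pv$sample_id)],
                     q_value = pv$q_value[match(rownames(R), pv$sample_id)])
    res_tab <- res_tab[order(res_tab$q_value, res_tab$p_value), , drop = FALSE]
    res_path <- file.path(out_dir, "resampling.tsv")
    out_fmt <- res_tab
    out_fmt$p_value <- sprintf("%.2E", res_tab$p_value)
    out_fmt$q_value <- sprintf("%.4f", res_tab$q_value)
    utils::write.table(out_fmt, res_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, resampling = res_path)
  }

  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    paste0("rpsurv version: ", as.character(utils::packageVersion("rpsurv"))),
    paste0("seed: ", cfg$seed),
    paste0("samples analysed: ", length(data$sample_ids)),
    paste0("genes: ", length(data$gene_names)),
    "dropped clinical records:",
    if (nrow(cleaned$dropped)) {
      paste0("  ", cleaned$dropped$sample_id, ": ", cleaned$dropped$reason)
    } else "  none",
    "config:",
    paste0("  ", utils::capture.output(utils::str(unclass(cfg), give.attr = FALSE)))
  )
  writeLines(log_lines, log_path)
  files <- c(files, log = log_path)

  invisible(list(fit = fit, resampling = res_tab, files = files))
}
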