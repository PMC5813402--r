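#' Clean clinical follow-up records
#'
#' Screens clinical records for internal consistency before survival times are
#' assembled. A record is kept only if (i) whenever both "days to last
#' follow-up" and "days to death" are present they agree, and (ii) a deceased
#' patient has a recorded "days to death". Records failing either rule, or
#' carrying no usable day field at all, are dropped with a machine-readable
#' reason.
#'
#' @param records Data frame with columns `sample_id`,
#'   `days_to_last_followup`, `days_to_death` and `vital_status`
#'   (`"alive"`/`"deceased"`, case-insensitive; `NA` allowed everywhere except
#'   `sample_id`).
#'
#' @return A list with `kept` (character vector of retained sample ids) and
#'   `dropped` (data frame with columns `sample_id`, `reason`; reasons are
#'   `"day_mismatch"`, `"deceased_missing_days"`, `"no_day_fields"`).
#'
#' @examples
#' rec <- data.frame(
#'   sample_id = c("a", "b", "c"),
#'   days_to_last_followup = c(100, 100, NA),
#'   days_to_death = c(100, 90, NA),
#'   vital_status = c("deceased", "deceased", "deceased")
#' )
#' clean_clinical(rec)
#' @export
clean_clinical <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no clinical records supplied")
  needed <- c("sample_id", "days_to_last_followup", "days_to_death", "vital_status")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  fup <- suppressWarnings(as.numeric(records$days_to_last_followup))
  dd <- suppressWarnings(as.numeric(records$days_to_death))
  vs <- tolower(trimws(as.character(records$vital_status)))
  vs[vs %in% c("", "na")] <- NA_character_

  reason <- rep(NA_character_, nrow(records))
  both <- !is.na(fup) & !is.na(dd)
  reason[both & fup != dd] <- "day_mismatch"
  dead_no_days <- !is.na(vs) & vs == "deceased" & is.na(dd)
  reason[is.na(reason) & dead_no_days] <- "deceased_missing_days"
  reason[is.na(reason) & is.na(fup) & is.na(dd)] <- "no_day_fields"

  keep <- is.na(reason)
  list(
    kept = as.character(records$sample_id[keep]),
    dropped = data.frame(
      sample_id = as.character(records$sample_id[!keep]),
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

# Map cleaned clinical records to (time, status): deceased -> days_to_death
# with an event, otherwise days_to_last_followup censored.
clinical_to_survival <- function(records) {
  fup <- suppressWarnings(as.numeric(records$days_to_last_followup))
  dd <- suppressWarnings(as.numeric(records$days_to_death))
  vs <- tolower(trimws(as.character(records$vital_status)))
  dead <- !is.na(vs) & vs == "deceased"
  time <- ifelse(dead, dd, fup)
  data.frame(
    sample_id = as.character(records$sample_id),
    time = time,
    status = as.integer(dead),
    stringsAsFactors = FALSE
  )
}

#' Read a clinical table
#'
#' Reads a TSV/CSV clinical table and normalises the column names used by
#' [clean_clinical()]. Column names are configurable so that tables using the
#' original attribute spellings ("Days to last follow-up", "Days to death",
#' "Vital status") can be read directly.
#'
#' @param path Path to a delimited text file with a header row.
#' @param id_col,followup_col,death_col,status_col Column names in the file.
#' @param sep Field separator; default tab, use `","` for CSV.
#' @return Data frame with standardised columns `sample_id`,
#'   `days_to_last_followup`, `days_to_death`, `vital_status`.
#' @export
read_clinical_table <- function(path,
                                id_col = "sample_id",
                                followup_col = "days_to_last_followup",
                                death_col = "days_to_death",
                                status_col = "vital_status",
                                sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  pick <- function(col, what) {
    if (!col %in% names(tab)) stop("clinical table has no column '", col, "' (", what, ")")
    tab[[col]]
  }
  data.frame(
    sample_id = as.character(pick(id_col, "sample id")),
    days_to_last_followup = suppressWarnings(as.numeric(pick(followup_col, "follow-up days"))),
    days_to_death = suppressWarnings(as.numeric(pick(death_col, "death days"))),
    vital_status = as.character(pick(status_col, "vital status")),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-expression matrix
#'
#' Reads a samples-by-genes TSV/CSV matrix (header row of gene symbols, first
#' column of sample ids). If the file turns out to be genes-by-samples, the
#' orientation is auto-detected by overlap of identifiers with `expect_ids`
#' and the matrix is transposed, with a message.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; default tab.
#' @param expect_ids Optional character vector of sample ids used to
#'   auto-detect orientation.
#' @return Numeric matrix with sample ids as rownames and genes as colnames.
#' @export
read_expression_matrix <- function(path, sep = "\t", expect_ids = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", row.names = 1)
  X <- as.matrix(tab)
  storage.mode(X) <- "double"
  if (!is.null(expect_ids)) {
    row_hits <- length(intersect(rownames(X), expect_ids))
    col_hits <- length(intersect(colnames(X), expect_ids))
    if (col_hits > row_hits) {
      message("expression matrix looks transposed (samples in columns); transposing")
      X <- t(X)
    }
  }
  X
}

#' Read a plain-text gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
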