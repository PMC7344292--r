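# Readers and writers for delimited omics matrices and survival tables.
# TSV is the canonical dialect (TCGA FireBrowse-style matrices are
# tab-delimited); the delimiter is configurable. All patient alignment in
# the package is by ID, never by row order.

#' Read an omics matrix from delimited text
#'
#' Expects a header row of feature IDs and a first column of patient IDs.
#' Rows (patients) and then columns (features) with more than
#' `max_missing` missing values are dropped with a message; remaining
#' missing values are imputed by the feature median; constant
#' (zero-variance) features are dropped with a message.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @param data_type platform label attached to the matrix (defaults to the
#'   file name without extension).
#' @param max_missing maximum tolerated missing fraction per row/column.
#' @return A validated omics matrix (see [omics_matrix()]).
#' @export
read_omics_matrix <- function(path, delimiter = "\t", data_type = NULL,
                              max_missing = 0.2) {
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) cfa_stop(sprintf("'%s': expected patient IDs plus >= 1 feature column", path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    cfa_stop(sprintf("'%s': duplicate patient IDs: %s", path,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  feat <- df[, -1L, drop = FALSE]
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(num))
      if (length(bad)) {
        cfa_stop(sprintf("'%s': non-numeric value '%s' at row %d, column '%s'",
                         path, col[bad[1L]], bad[1L], names(feat)[j]))
      }
      feat[[j]] <- num
    }
  }
  x <- as.matrix(feat)
  rownames(x) <- ids

  row_miss <- rowMeans(is.na(x))
  if (any(row_miss > max_missing)) {
    message(sprintf("read_omics_matrix: dropping %d patient(s) with > %.0f%% missing values",
                    sum(row_miss > max_missing), 100 * max_missing))
    x <- x[row_miss <= max_missing, , drop = FALSE]
  }
  col_miss <- colMeans(is.na(x))
  if (any(col_miss > max_missing)) {
    message(sprintf("read_omics_matrix: dropping %d feature(s) with > %.0f%% missing values",
                    sum(col_miss > max_missing), 100 * max_missing))
    x <- x[, col_miss <= max_missing, drop = FALSE]
  }
  if (anyNA(x)) {
    message(sprintf("read_omics_matrix: imputing %d missing value(s) by feature median",
                    sum(is.na(x))))
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- stats::median(x[, j], na.rm = TRUE)
    }
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("read_omics_matrix: dropping %d constant feature(s)",
                    sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (is.null(data_type)) {
    data_type <- sub("\\.[^.]*$", "", basename(path))
  }
  omics_matrix(x, data_type = data_type)
}

#' Read a survival table from delimited text
#'
#' Expects columns `patient_id`, `time`, `event` (by name). Rows with a
#' missing time or event are dropped with a message; the remaining table
#' must have strictly positive times and events in \{0, 1\}.
#'
#' @inheritParams read_omics_matrix
#' @return A validated `data.frame` with columns `patient_id`, `time`,
#'   `event`.
#' @export
read_survival <- function(path, delimiter = "\t") {
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(df))) {
    cfa_stop(sprintf("'%s': survival table needs columns %s", path,
                     paste(need, collapse = ", ")))
  }
  df <- df[, need]
  incomplete <- is.na(df$time) | is.na(df$event)
  if (any(incomplete)) {
    message(sprintf("read_survival: dropping %d patient(s) with missing time/event",
                    sum(incomplete)))
    df <- df[!incomplete, ]
  }
  validate_survival(df)
}

# Shared survival-table validator used by every consumer.
validate_survival <- function(surv) {
  if (!is.data.frame(surv) ||
      !all(c("patient_id", "time", "event") %in% names(surv))) {
    cfa_stop("survival table must have columns patient_id, time, event")
  }
  surv$patient_id <- as.character(surv$patient_id)
  if (anyDuplicated(surv$patient_id)) {
    cfa_stop(sprintf("duplicate patient IDs in survival table: %s",
                     paste(unique(surv$patient_id[duplicated(surv$patient_id)]),
                           collapse = ", ")))
  }
  if (!is.numeric(surv$time) || any(!is.finite(surv$time)) ||
      any(surv$time <= 0)) {
    cfa_stop("survival times must be finite and strictly positive")
  }
  if (!all(surv$event %in% c(0, 1))) {
    cfa_stop("event indicator must be 0 (censored) or 1 (event)")
  }
  surv$event <- as.integer(surv$event)
  rownames(surv) <- NULL
  surv
}

#' Write pipeline results to a directory
#'
#' Writes a `"subtype_result"` as `subtypes.tsv` (patient_id, subtype),
#' `consensus.tsv` (n x n co-clustering frequencies) and `partitions.json`
#' (per-representation provenance), or a `"risk_result"` as `risk.tsv`
#' (patient_id, risk_score) and `per_representation_risks.tsv`. Output is
#' deterministic for identical results: stable ordering and fixed
#' 6-significant-digit float formatting.
#'
#' @param result a `"subtype_result"` or `"risk_result"`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(result, out_dir) {
  UseMethod("write_results")
}

fmt_num <- function(x) sprintf("%.6g", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @export
write_results.subtype_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- write_tsv(data.frame(patient_id = names(result$labels),
                             subtype = as.integer(result$labels)),
                  file.path(out_dir, "subtypes.tsv"))
  cons <- result$consensus
  cons_df <- data.frame(patient_id = rownames(cons),
                        apply(cons, 2L, fmt_num),
                        check.names = FALSE)
  f2 <- write_tsv(cons_df, file.path(out_dir, "consensus.tsv"))
  prov <- list(
    k_final = result$k_final,
    partitions = lapply(result$partitions, function(p) {
      list(k = p$k, sse = p$sse, source = p$source,
           labels = as.integer(p$labels))
    }))
  if (!is.null(result$representation_meta)) {
    prov$representations <- result$representation_meta
  }
  f3 <- file.path(out_dir, "partitions.json")
  jsonlite::write_json(prov, f3, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(c(f1, f2, f3))
}

#' @export
write_results.risk_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- write_tsv(data.frame(patient_id = result$patient_ids,
                             risk_score = fmt_num(result$risk)),
                  file.path(out_dir, "risk.tsv"))
  pr <- result$per_representation_risks
  pr_df <- data.frame(patient_id = rownames(pr), apply(pr, 2L, fmt_num),
                      check.names = FALSE)
  f2 <- write_tsv(pr_df, file.path(out_dir, "per_representation_risks.tsv"))
  invisible(c(f1, f2))
}

#' Write a synthetic cohort as delimited text
#'
#' Writes each omics as `<data_type>.tsv` (patients x features), the
#' survival table as `survival.tsv`, and the planted truth as `truth.tsv`
#' (patient_id, subtype, true_risk).
#'
#' @param cohort a `"synthetic_cohort"` (see [simulate_cohort()]).
#' @param out_dir output directory.
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in cohort$omics) {
    df <- data.frame(patient_id = rownames(m), apply(m, 2L, fmt_num),
                     check.names = FALSE)
    paths <- c(paths, write_tsv(df, file.path(
      out_dir, paste0(omics_data_type(m), ".tsv"))))
  }
  if (!is.null(cohort$survival)) {
    sv <- cohort$survival
    sv$time <- fmt_num(sv$time)
    paths <- c(paths, write_tsv(sv, file.path(out_dir, "survival.tsv")))
  }
  truth <- data.frame(patient_id = names(cohort$true_labels),
                      subtype = as.integer(cohort$true_labels))
  if (!is.null(cohort$true_risk)) truth$true_risk <- fmt_num(cohort$true_risk)
  paths <- c(paths, write_tsv(truth, file.path(out_dir, "truth.tsv")))
  invisible(paths)
}
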