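# The omics-matrix container: a plain numeric matrix, patients in rows
# (rownames = patient IDs), features in columns (colnames = feature IDs),
# with a "data_type" attribute naming the platform.

#' Construct a validated omics matrix
#'
#' The package's canonical per-platform container: a numeric matrix with
#' patients in rows and features in columns. Patient and feature identifiers
#' must be unique; values must be finite (missing-value handling belongs to
#' [read_omics_matrix()], which imputes before construction).
#'
#' @param values numeric matrix, `n_patients x p_features`.
#' @param patient_ids,feature_ids character vectors of unique identifiers;
#'   taken from `dimnames(values)` when omitted.
#' @param data_type platform label, e.g. `"mRNA"`, `"methylation"`.
#' @return The matrix with dimnames set and a `data_type` attribute.
#' @export
#' @examples
#' m <- omics_matrix(matrix(rnorm(20), 4, 5), data_type = "mRNA")
#' omics_data_type(m)
omics_matrix <- function(values, patient_ids = NULL, feature_ids = NULL,
                         data_type = "omics") {
  if (!is.matrix(values) || !is.numeric(values)) {
    cfa_stop("`values` must be a numeric matrix (patients x features)")
  }
  patient_ids <- patient_ids %||% rownames(values) %||%
    paste0("P", seq_len(nrow(values)))
  feature_ids <- feature_ids %||% colnames(values) %||%
    paste0("F", seq_len(ncol(values)))
  if (length(patient_ids) != nrow(values)) {
    cfa_stop("`patient_ids` length does not match the number of rows")
  }
  if (length(feature_ids) != ncol(values)) {
    cfa_stop("`feature_ids` length does not match the number of columns")
  }
  if (anyDuplicated(patient_ids)) {
    cfa_stop(sprintf("duplicate patient IDs: %s",
                     paste(unique(patient_ids[duplicated(patient_ids)]),
                           collapse = ", ")))
  }
  if (anyDuplicated(feature_ids)) {
    cfa_stop(sprintf("duplicate feature IDs: %s",
                     paste(unique(feature_ids[duplicated(feature_ids)]),
                           collapse = ", ")))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    cfa_stop("omics matrix contains missing or non-finite values")
  }
  dimnames(values) <- list(as.character(patient_ids),
                           as.character(feature_ids))
  attr(values, "data_type") <- data_type
  values
}

#' @rdname omics_matrix
#' @param m an omics matrix.
#' @export
omics_data_type <- function(m) {
  attr(m, "data_type") %||% "omics"
}

# Internal: assert a matrix-like omics input, returning it with dimnames.
as_omics <- function(m, what = "omics matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    cfa_stop(sprintf("%s must be a numeric matrix", what))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("F", seq_len(ncol(m)))
  m
}

# Internal: check all omics share one patient-ID set; reorder each to the
# ordering of the first. Alignment is always by ID, never by row position.
align_omics <- function(omics_list) {
  if (length(omics_list) == 0L) cfa_stop("at least one omics matrix required")
  omics_list <- lapply(omics_list, as_omics)
  ref <- rownames(omics_list[[1L]])
  for (d in seq_along(omics_list)) {
    ids <- rownames(omics_list[[d]])
    extra <- setdiff(ids, ref)
    missing <- setdiff(ref, ids)
    if (length(extra) || length(missing)) {
      cfa_stop(sprintf(
        "patient IDs differ across omics matrices (matrix %d: %s)", d,
        paste(utils::head(c(
          if (length(missing)) paste0("missing ", missing),
          if (length(extra)) paste0("extra ", extra)), 5L), collapse = ", ")))
    }
    dt <- omics_data_type(omics_list[[d]])
    omics_list[[d]] <- omics_list[[d]][ref, , drop = FALSE]
    attr(omics_list[[d]], "data_type") <- dt
  }
  omics_list
}
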