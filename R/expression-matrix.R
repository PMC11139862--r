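#' Gene-by-sample expression matrix
#'
#' Lightweight container for a non-negative gene x sample abundance matrix
#' (TPM) or its log2 transform. Genes are rows, samples are columns; both
#' dimensions carry unique identifiers.
#'
#' @param values numeric matrix with rownames (gene IDs) and colnames
#'   (sample IDs). Zero columns are allowed (empty sample set).
#' @param transform either `"raw_tpm"` or `"log2_tpm"`.
#' @return an object of class `ExpressionMatrix` with fields `values` and
#'   `transform`.
#' @export
expression_matrix <- function(values, transform = c("raw_tpm", "log2_tpm")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have rownames (gene IDs)")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have colnames (sample IDs)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (ncol(values) > 0 && anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression values must not contain NA")
  if (transform == "raw_tpm" && length(values) && min(values) < 0)
    stop("raw TPM values must be non-negative")
  structure(list(values = values, transform = transform),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

as_values <- function(x) {
  if (is_expression_matrix(x)) x$values else x
}

#' Canonical collection timepoints
#'
#' The eight canonical longitudinal collection timepoints (enrolment through
#' twelve months) and their encoding in hours. The hour encoding gives a
#' single numeric axis for regression and plotting: 28 days = 672 h,
#' 6 months = 4380 h, 12 months = 8760 h.
#'
#' @return named numeric vector mapping timepoint label to hours, in
#'   canonical order.
#' @export
canonical_timepoints <- function() {
  c("0h" = 0, "6h" = 6, "24h" = 24, "48h" = 48, "72h" = 72,
    "28d" = 672, "6m" = 4380, "12m" = 8760)
}

#' Validate cohort metadata
#'
#' Checks a per-sample metadata table: required columns, canonical timepoint
#' labels, unique (subject, timepoint) pairs, and the contract that healthy
#' samples carry outcome `not_applicable`. Derives the `hours` column from
#' the timepoint label.
#'
#' @param meta data.frame with columns `sample_id`, `subject_id`,
#'   `timepoint`, `group` (healthy/sepsis), `outcome` (survived/died/
#'   unknown/not_applicable), `age`, `sex` (F/M). An `hours` column is
#'   (re)derived from `timepoint`.
#' @return the validated data.frame with an `hours` column.
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "subject_id", "timepoint", "group", "outcome",
                "age", "sex")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  tp <- canonical_timepoints()
  bad <- setdiff(unique(as.character(meta$timepoint)), names(tp))
  if (length(bad))
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  if (!all(meta$group %in% c("healthy", "sepsis")))
    stop("group must be 'healthy' or 'sepsis'")
  meta$outcome <- as.character(meta$outcome)
  meta$outcome[meta$group == "sepsis" & (is.na(meta$outcome) | meta$outcome == "")] <- "unknown"
  ok_out <- c("survived", "died", "unknown", "not_applicable")
  if (!all(meta$outcome %in% ok_out))
    stop("outcome must be one of: ", paste(ok_out, collapse = ", "))
  if (any(meta$group == "healthy" & meta$outcome != "not_applicable"))
    stop("healthy samples must have outcome 'not_applicable'")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  key <- paste(meta$subject_id, meta$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    d <- meta[duplicated(key), , drop = FALSE]
    stop("duplicate (subject_id, timepoint) pair: ",
         paste(d$subject_id[1], d$timepoint[1]))
  }
  meta$hours <- unname(tp[as.character(meta$timepoint)])
  meta
}
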