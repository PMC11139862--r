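#' Read a gene x sample expression TSV
#'
#' First column must be `gene_id`; remaining columns are numeric sample
#' columns. Duplicate gene or sample IDs, ragged rows, and negative values
#' (for raw TPM) are rejected with informative errors.
#'
#' @param path file path.
#' @param transform transform tag to stamp on the result.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, transform = "raw_tpm") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged row at line ", which(nf != nf[1])[1], " of ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene ID: ", genes[duplicated(genes)][1])
  samples <- names(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicated sample ID: ", samples[duplicated(samples)][1])
  V <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(V)) stop("non-numeric expression values in ", path)
  dimnames(V) <- list(genes, samples)
  if (transform == "raw_tpm" && length(V) && min(V) < 0) {
    ij <- arrayInd(which.min(V), dim(V))
    stop("negative value for gene ", genes[ij[1]], ", sample ", samples[ij[2]])
  }
  expression_matrix(V, transform)
}

format_num <- function(x, digits = NULL) {
  if (is.null(digits)) sprintf("%.17g", x) else sprintf("%.*g", digits, x)
}

#' Write a gene x sample expression TSV
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @param digits significant digits (`NULL` = full precision, which
#'   round-trips doubles exactly).
#' @export
write_expression_tsv <- function(em, path, digits = NULL) {
  V <- as_values(em)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(V)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(V)), function(i)
    paste(c(rownames(V)[i], format_num(V[i, ], digits)), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read cohort metadata from CSV
#'
#' Validates required columns, canonical timepoint labels, and the
#' healthy-outcome contract; derives `hours`; sepsis rows with a missing
#' outcome become `unknown`.
#'
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Write cohort metadata to CSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata_csv <- function(meta, path) {
  cols <- c("sample_id", "subject_id", "timepoint", "hours", "group",
            "outcome", "age", "sex")
  utils::write.csv(meta[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Duplicate genes within a set are collapsed with a warning.
#'
#' @param path file path.
#' @return named list of character vectors; attribute `description` carries
#'   per-set descriptions.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", fields[1], "' collapsed")
      genes <- unique(genes)
    }
    if (length(genes) == 0L)
      stop("set '", fields[1], "' is empty after deduplication (line ", i, ")")
    sets[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors; optional `description`
#'   attribute.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_manifest <- function(entries, path) {
  writeLines(paste0(names(entries), ": ", vapply(entries, function(e)
    paste(format(e, trim = TRUE), collapse = " "), character(1))), path)
  invisible(path)
}

#' Write a factorization archive
#'
#' Directory with `A.tsv` (genes x K), `P.tsv` (K x samples), `loss.tsv`
#' and a plain-text manifest (K, seed, sparsity weights, iterations,
#' convergence). Matrices are written at full precision.
#'
#' @param result a `FactorizationResult`.
#' @param dir output directory (created if needed).
#' @export
write_factorization <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  A_em <- expression_matrix(result$A, "raw_tpm")
  write_expression_tsv(A_em, file.path(dir, "A.tsv"))
  con <- file(file.path(dir, "P.tsv"), "w")
  writeLines(paste(c("pattern", colnames(result$P)), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(result$P)), function(i)
    paste(c(rownames(result$P)[i], format_num(result$P[i, ])), collapse = "\t"),
    character(1)), con)
  close(con)
  utils::write.table(data.frame(iteration = seq_along(result$loss_trace),
                                objective = result$loss_trace),
                     file.path(dir, "loss.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_manifest(list(K = result$K, seed = result$seed,
                      lambda_A = result$sparsity_weights[["lambda_A"]],
                      lambda_P = result$sparsity_weights[["lambda_P"]],
                      iterations = result$n_iter,
                      converged = result$converged),
                 file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a factorization archive written by [write_factorization()]
#' @param dir archive directory.
#' @return a `FactorizationResult` (without the loss trace details beyond
#'   the stored objective values).
#' @export
read_factorization <- function(dir) {
  A <- as_values(read_expression_tsv(file.path(dir, "A.tsv")))
  pdf <- utils::read.delim(file.path(dir, "P.tsv"), check.names = FALSE)
  P <- as.matrix(pdf[, -1, drop = FALSE])
  rownames(P) <- pdf[[1]]
  loss <- utils::read.delim(file.path(dir, "loss.tsv"))
  man <- readLines(file.path(dir, "manifest.txt"))
  get <- function(key) sub(paste0("^", key, ": "), "", man[grepl(paste0("^", key, ":"), man)])
  structure(list(A = A, P = P, K = as.integer(get("K")),
                 loss_trace = loss$objective,
                 converged = as.logical(get("converged")),
                 n_iter = as.integer(get("iterations")),
                 seed = as.integer(get("seed")),
                 sparsity_weights = c(lambda_A = as.numeric(get("lambda_A")),
                                      lambda_P = as.numeric(get("lambda_P")))),
            class = "FactorizationResult")
}
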