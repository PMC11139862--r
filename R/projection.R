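#' Intersect the gene universes of an amplitude matrix and a target
#'
#' Exact, case-sensitive identifier matching, returned in a canonical order
#' (sorted gene ID).
#'
#' @param A amplitude matrix with gene rownames.
#' @param target an [expression_matrix()] or matrix with gene rownames.
#' @return list with `genes` (shared IDs, sorted), `source_idx`, `target_idx`
#'   (row indices into `A` and the target), and `shared_fraction` (fraction
#'   of source genes found in the target).
#' @export
intersect_genes <- function(A, target) {
  tv <- as_values(target)
  shared <- sort(intersect(rownames(A), rownames(tv)))
  if (length(shared) == 0L) stop("no shared genes between source and target")
  list(genes = shared,
       source_idx = match(shared, rownames(A)),
       target_idx = match(shared, rownames(tv)),
       shared_fraction = length(shared) / nrow(A))
}

#' Project target samples into a learned latent space
#'
#' For each target column `d`, solves `min_w ||d_shared - A_shared w||^2`
#' over the shared-gene rows, either unconstrained (`ols`; minimum-norm
#' solution via SVD pseudoinverse when `A_shared` is rank deficient) or with
#' `w >= 0` (`nnls`, Lawson-Hanson). Columns are independent; no intercept
#' and no target re-centering by default.
#'
#' @param A amplitude matrix (genes x K) with gene rownames.
#' @param target an [expression_matrix()] (log2 scale expected) or matrix.
#' @param method `"ols"` or `"nnls"`.
#' @param min_shared_fraction minimum fraction of source genes that must be
#'   found in the target (default 0.5); guards against identifier mismatch.
#' @param allow_low_overlap set `TRUE` to warn-and-proceed below the
#'   threshold instead of erroring.
#' @param center per-gene centering of both `A`'s gene rows means? If TRUE,
#'   subtracts the shared-gene row means of the target from the target
#'   (optional; off by default).
#' @return a `ProjectionResult`: `weights` (K x target samples),
#'   `method_tag`, `n_shared_genes`, `shared_fraction`, `target_ids`.
#' @export
project_samples <- function(A, target, method = c("ols", "nnls"),
                            min_shared_fraction = 0.5,
                            allow_low_overlap = FALSE, center = FALSE) {
  method <- match.arg(method)
  tv <- as_values(target)
  ix <- intersect_genes(A, tv)
  if (ix$shared_fraction < min_shared_fraction) {
    msg <- sprintf("only %.1f%% of source genes found in target (minimum %.1f%%)",
                   100 * ix$shared_fraction, 100 * min_shared_fraction)
    if (!allow_low_overlap) stop(msg, "; set allow_low_overlap = TRUE to proceed")
    warning(msg, "; proceeding")
  }
  As <- A[ix$source_idx, , drop = FALSE]
  Ts <- tv[ix$target_idx, , drop = FALSE]
  if (center) Ts <- Ts - rowMeans(Ts)

  K <- ncol(A)
  if (method == "ols") {
    sv <- svd(As)
    pos <- sv$d > max(dim(As)) * .Machine$double.eps * max(sv$d, 1)
    if (sum(pos) < K)
      warning("A is rank deficient over the shared genes; ",
              "returning minimum-norm solutions")
    dinv <- ifelse(pos, 1 / sv$d, 0)
    W <- sv$v %*% (dinv * crossprod(sv$u, Ts))
  } else {
    W <- apply(Ts, 2, function(d) pracma::lsqnonneg(As, d)$x)
    W <- matrix(W, nrow = K)
  }
  dimnames(W) <- list(colnames(A), colnames(tv))
  structure(list(weights = W, method_tag = method,
                 n_shared_genes = length(ix$genes),
                 shared_fraction = ix$shared_fraction,
                 target_ids = colnames(tv)),
            class = "ProjectionResult")
}

#' @export
print.ProjectionResult <- function(x, ...) {
  cat(sprintf("ProjectionResult (%s): %d patterns x %d targets over %d shared genes (%.0f%% of source)\n",
              x$method_tag, nrow(x$weights), ncol(x$weights),
              x$n_shared_genes, 100 * x$shared_fraction))
  invisible(x)
}

#' Project target samples onto stored principal components
#'
#' Centers the target's shared-gene rows with the gene means stored at PCA
#' time and multiplies by the stored loadings, reproducing the source scores
#' for the source data itself.
#'
#' @param pca a `PCAResult` from [run_pca()].
#' @param target an [expression_matrix()] (log2 scale expected) or matrix.
#' @return matrix of scores, target samples x components.
#' @export
project_onto_pcs <- function(pca, target) {
  tv <- as_values(target)
  shared <- sort(intersect(names(pca$gene_means), rownames(tv)))
  if (length(shared) == 0L) stop("no shared genes between PCA source and target")
  Xc <- tv[shared, , drop = FALSE] - pca$gene_means[shared]
  scores <- crossprod(Xc, pca$loadings[shared, , drop = FALSE])
  rownames(scores) <- colnames(tv)
  scores
}
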