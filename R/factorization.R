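#' Log2-transform a TPM expression matrix
#'
#' @param D an [expression_matrix()] with `transform == "raw_tpm"`.
#' @param pseudocount positive offset added before taking log2 (default 1, so
#'   TPM 0 maps to 0).
#' @return an [expression_matrix()] with `transform == "log2_tpm"`.
#' @export
log_transform <- function(D, pseudocount = 1) {
  stopifnot(is_expression_matrix(D))
  if (D$transform != "raw_tpm")
    stop("input is already log-transformed")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (length(D$values) && min(D$values) < 0) stop("negative input value")
  expression_matrix(log2(D$values + pseudocount), "log2_tpm")
}

#' Filter genes before factorization
#'
#' Drops genes with zero variance across samples or detected (value > 0) in
#' fewer than `min_detect_frac` of samples. Guards the multiplicative
#' updates against degenerate all-zero rows.
#'
#' @param D an [expression_matrix()].
#' @param min_detect_frac minimum fraction of samples with a positive value.
#' @return the filtered [expression_matrix()].
#' @export
filter_genes <- function(D, min_detect_frac = 0.05) {
  stopifnot(is_expression_matrix(D))
  v <- D$values
  detected <- rowMeans(v > 0) >= min_detect_frac
  vars <- apply(v, 1, stats::var)
  keep <- detected & vars > 0
  if (!any(keep)) stop("no genes pass the filter")
  expression_matrix(v[keep, , drop = FALSE], D$transform)
}

nmf_objective <- function(D, A, P, lambda_A, lambda_P) {
  R <- D - A %*% P
  sum(R * R) + lambda_A * sum(A) + lambda_P * sum(P)
}

#' Non-negative matrix factorization of an expression matrix
#'
#' Decomposes a non-negative gene x sample matrix `D` into an amplitude
#' matrix `A` (genes x K) and a pattern matrix `P` (K x samples) so that
#' `D ~ A %*% P`, by minimizing
#' `||D - A P||_F^2 + lambda_A * sum(A) + lambda_P * sum(P)`
#' with L1-penalized multiplicative updates under random restarts; the
#' restart with the lowest final objective is returned. Rows of `P` are
#' rescaled to unit maximum with the inverse scale folded into `A`, which
#' leaves the product unchanged and fixes the scale indeterminacy.
#'
#' @param D an [expression_matrix()] (any transform tag) or numeric matrix;
#'   all entries must be non-negative.
#' @param K number of patterns, `1 <= K <= min(genes, samples)`. The study
#'   configuration this package mirrors used `K = 30`.
#' @param sparsity length-2 numeric `(lambda_A, lambda_P)`; default
#'   `0.01 * mean(D)` for both.
#' @param seed integer; restart `r` uses `seed + r`.
#' @param tol stop when the relative objective change drops below this.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param n_restarts random restarts.
#' @return a `FactorizationResult`: `A`, `P`, `K`, `loss_trace` (per-iteration
#'   objective of the winning restart), `converged`, `n_iter`, `seed`,
#'   `sparsity_weights`.
#' @export
fit_nmf <- function(D, K = 30L, sparsity = NULL, seed = 1L, tol = 1e-5,
                    max_iter = 2000L, n_restarts = 5L) {
  V <- as_values(D)
  if (length(V) && min(V) < 0) stop("fit_nmf requires a non-negative matrix")
  G <- nrow(V); S <- ncol(V)
  if (K < 1L || K > min(G, S))
    stop("K must satisfy 1 <= K <= min(genes, samples); got K = ", K)
  mD <- mean(V)
  if (is.null(sparsity)) sparsity <- rep(0.01 * mD, 2L)
  lambda_A <- sparsity[[1]]; lambda_P <- sparsity[[2]]
  eps <- 1e-12

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    scale0 <- if (mD > 0) mD / K else 1
    A <- matrix(stats::runif(G * K) * scale0, nrow = G)
    P <- matrix(stats::runif(K * S) * scale0, nrow = K)
    trace <- numeric(0)
    obj <- nmf_objective(V, A, P, lambda_A, lambda_P)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      # A <- A * (2 D P') / (2 A P P' + lambda_A)
      PPt <- tcrossprod(P)
      A <- A * (2 * tcrossprod(V, P)) / (2 * A %*% PPt + lambda_A + eps)
      AtA <- crossprod(A)
      P <- P * (2 * crossprod(A, V)) / (2 * AtA %*% P + lambda_P + eps)
      new_obj <- nmf_objective(V, A, P, lambda_A, lambda_P)
      trace <- c(trace, new_obj)
      if (obj > 0 && abs(obj - new_obj) / obj < tol) {
        converged <- TRUE
        obj <- new_obj
        break
      }
      obj <- new_obj
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(A = A, P = P, objective = obj, loss_trace = trace,
                   converged = converged, n_iter = it, restart = r)
    }
  }

  A <- best$A; P <- best$P
  # fold P row scales into A: rows of P get unit maximum
  scales <- apply(P, 1, max)
  scales[scales <= 0] <- 1
  P <- P / scales
  A <- sweep(A, 2, scales, "*")
  pat_ids <- sprintf("P%02d", seq_len(K))
  dimnames(A) <- list(rownames(V), pat_ids)
  dimnames(P) <- list(pat_ids, colnames(V))

  structure(list(A = A, P = P, K = as.integer(K),
                 loss_trace = best$loss_trace, converged = best$converged,
                 n_iter = best$n_iter, seed = as.integer(seed),
                 sparsity_weights = c(lambda_A = lambda_A, lambda_P = lambda_P)),
            class = "FactorizationResult")
}

#' @export
print.FactorizationResult <- function(x, ...) {
  cat(sprintf("FactorizationResult: %d genes x %d samples, K = %d (%s, %d iterations)\n",
              nrow(x$A), ncol(x$P), x$K,
              if (x$converged) "converged" else "max_iter reached", x$n_iter))
  invisible(x)
}

#' Relative Frobenius reconstruction error
#'
#' `||D - A P||_F / ||D||_F`.
#'
#' @param result a `FactorizationResult` (or list with `A`, `P`).
#' @param D the matrix that was factorized.
#' @return a number in `[0, Inf)`; 0 for an exact factorization, 1 when
#'   `A P` is identically zero and `D` is not.
#' @export
reconstruction_error <- function(result, D) {
  V <- as_values(D)
  if (nrow(result$A) != nrow(V) || ncol(result$P) != ncol(V))
    stop("dimension mismatch between factorization and matrix")
  R <- V - result$A %*% result$P
  sqrt(sum(R * R)) / sqrt(sum(V * V))
}

#' Principal component analysis of an expression matrix
#'
#' Gene-centered (no variance scaling) PCA via singular-value decomposition.
#' Each component's sign is fixed so its largest-magnitude gene loading is
#' positive; gene means are stored so external samples can be projected with
#' [project_onto_pcs()].
#'
#' @param D an [expression_matrix()] (typically log2) or numeric matrix.
#' @param n_components number of components, at most `min(genes, samples)`.
#' @return a `PCAResult`: `loadings` (genes x components, orthonormal),
#'   `scores` (samples x components), `explained_variance_fraction`,
#'   `gene_means`.
#' @export
run_pca <- function(D, n_components = 2L) {
  V <- as_values(D)
  if (n_components > min(dim(V)))
    stop("n_components exceeds min(genes, samples)")
  gene_means <- rowMeans(V)
  Xc <- V - gene_means
  total_var <- sum(Xc * Xc)
  if (total_var == 0) {
    warning("constant matrix: all components have zero variance")
    loadings <- matrix(0, nrow(V), n_components,
                       dimnames = list(rownames(V), paste0("PC", seq_len(n_components))))
    scores <- matrix(0, ncol(V), n_components,
                     dimnames = list(colnames(V), paste0("PC", seq_len(n_components))))
    return(structure(list(loadings = loadings, scores = scores,
                          explained_variance_fraction = rep(0, n_components),
                          gene_means = gene_means), class = "PCAResult"))
  }
  sv <- svd(Xc, nu = n_components, nv = n_components)
  loadings <- sv$u
  scores <- sv$v %*% diag(sv$d[seq_len(n_components)], n_components)
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(rownames(V), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(colnames(V), paste0("PC", seq_len(n_components)))
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_fraction = sv$d[seq_len(n_components)]^2 / sum(sv$d^2),
                 gene_means = gene_means),
            class = "PCAResult")
}

#' Rank genes by amplitude within one pattern
#'
#' Genes ordered by descending amplitude in the chosen pattern column; ties
#' broken by gene ID. Rank 1 is the highest amplitude.
#'
#' @param result a `FactorizationResult` (or any list with an `A` matrix
#'   carrying gene rownames).
#' @param pattern_index column index into `A`.
#' @return data.frame with columns `gene`, `rank`, `amplitude`.
#' @export
rank_genes_by_amplitude <- function(result, pattern_index) {
  A <- result$A
  if (pattern_index < 1 || pattern_index > ncol(A))
    stop("pattern_index out of range 1..", ncol(A))
  genes <- rownames(A)
  amp <- A[, pattern_index]
  ord <- order(-amp, genes)
  data.frame(gene = genes[ord], rank = seq_along(ord),
             amplitude = unname(amp[ord]), stringsAsFactors = FALSE)
}

#' Match recovered patterns to ground-truth patterns
#'
#' Greedy matching on the cosine-similarity matrix between rows of a
#' recovered pattern matrix and rows of a reference pattern matrix:
#' repeatedly picks the highest remaining similarity and removes both rows.
#'
#' @param P_hat recovered K x samples matrix.
#' @param P_ref reference K_ref x samples matrix (same sample order).
#' @return data.frame with `recovered`, `reference`, `cosine` for each
#'   matched pair (min(K, K_ref) rows).
#' @export
match_patterns <- function(P_hat, P_ref) {
  if (ncol(P_hat) != ncol(P_ref)) stop("sample dimensions differ")
  norm_rows <- function(M) {
    n <- sqrt(rowSums(M^2)); n[n == 0] <- 1; M / n
  }
  S <- norm_rows(P_hat) %*% t(norm_rows(P_ref))
  out <- list()
  for (i in seq_len(min(nrow(P_hat), nrow(P_ref)))) {
    ij <- arrayInd(which.max(S), dim(S))
    out[[i]] <- data.frame(recovered = ij[1], reference = ij[2],
                           cosine = S[ij[1], ij[2]])
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
  }
  do.call(rbind, out)
}
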