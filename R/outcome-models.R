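#' Restrict a cohort to subjects with known 28-day mortality
#'
#' Drops healthy donors (no mortality outcome) and sepsis subjects whose
#' 28-day outcome is unknown, the filter applied before all mortality
#' modeling.
#'
#' @param meta cohort metadata (see [validate_metadata()]).
#' @return the filtered metadata; attribute `n_subjects` carries the number
#'   of retained subjects.
#' @export
filter_known_outcome <- function(meta) {
  keep <- meta$group == "sepsis" & meta$outcome %in% c("survived", "died")
  out <- meta[keep, , drop = FALSE]
  n <- length(unique(out$subject_id))
  if (n == 0L) stop("no subjects with known 28-day mortality remain")
  attr(out, "n_subjects") <- n
  out
}

#' Area under the ROC curve via the rank (Mann-Whitney) formulation
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative; ties get average ranks (counted 1/2).
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical or two-level vector; `TRUE` (or the second level)
#'   is the positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- sort(unique(as.character(labels)))
  if (length(u) == 1L) stop("labels contain a single class")
  if (length(u) > 2L) stop("labels must be binary")
  pos <- if ("died" %in% u) "died" else u[2]
  as.character(labels) == pos
}

#' Logistic AUROC of one pattern at one timepoint
#'
#' Fits `died ~ pattern + age + sex` on the sepsis samples of a single
#' timepoint (known outcomes only) and computes the in-sample AUROC of the
#' model's predicted probabilities by the rank formulation.
#'
#' @param P pattern matrix (patterns x samples, sample colnames).
#' @param meta cohort metadata.
#' @param pattern_index row of `P`.
#' @param timepoint canonical timepoint label.
#' @param covariates subset of `c("age", "sex")` to adjust for.
#' @return list with `auroc`, `n_died`, `n_survived`, `converged`, `model`.
#' @export
pattern_logistic_auroc <- function(P, meta, pattern_index, timepoint,
                                   covariates = c("age", "sex")) {
  m <- filter_known_outcome(meta)
  m <- m[m$timepoint == timepoint & m$sample_id %in% colnames(P), , drop = FALSE]
  y <- m$outcome == "died"
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 subjects per outcome class at ", timepoint)
  df <- data.frame(y = y, pattern = P[pattern_index, m$sample_id])
  if ("age" %in% covariates) df$age <- m$age
  if ("sex" %in% covariates) df$sex_m <- as.integer(m$sex == "M")
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  list(auroc = auroc(stats::fitted(fit), y),
       n_died = sum(y), n_survived = sum(!y),
       converged = fit$converged && !any(is.na(stats::coef(fit))),
       model = fit)
}

#' Per-pattern, per-timepoint logistic AUROC table
#'
#' Runs [pattern_logistic_auroc()] over all patterns and the requested
#' timepoints. Cells with fewer than 5 subjects in either outcome class are
#' flagged `unreliable`.
#'
#' @param P pattern matrix.
#' @param meta cohort metadata.
#' @param timepoints timepoint labels; default the five acute collections.
#' @param covariates adjustment covariates.
#' @return data.frame (class `AurocTable`) with columns `pattern`,
#'   `timepoint`, `auroc`, `n_died`, `n_survived`, `unreliable`.
#' @export
auroc_table <- function(P, meta,
                        timepoints = c("0h", "6h", "24h", "48h", "72h"),
                        covariates = c("age", "sex")) {
  rows <- list()
  for (k in seq_len(nrow(P))) {
    for (tp in timepoints) {
      fit <- pattern_logistic_auroc(P, meta, k, tp, covariates)
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = rownames(P)[k], timepoint = tp, auroc = fit$auroc,
        n_died = fit$n_died, n_survived = fit$n_survived,
        unreliable = min(fit$n_died, fit$n_survived) < 5L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("AurocTable", "data.frame")
  out
}

#' Classify patterns as prognostic, dynamic, or uninformative
#'
#' A pattern is *prognostic* if its AUROC reaches the threshold at enrolment
#' (0h); *dynamic* if it misses the threshold at enrolment but reaches it at
#' 48h or any later covered timepoint; otherwise *uninformative*.
#'
#' @param table an [auroc_table()] result (long data.frame with `pattern`,
#'   `timepoint`, `auroc`).
#' @param threshold AUROC threshold, default 0.70.
#' @return data.frame with `pattern` and `class`.
#' @export
classify_patterns <- function(table, threshold = 0.70) {
  if (!"0h" %in% table$timepoint)
    stop("AUROC table must include the 0h (enrolment) timepoint")
  tp <- canonical_timepoints()
  late <- names(tp)[tp >= 48]
  patterns <- unique(table$pattern)
  cls <- vapply(patterns, function(p) {
    sub <- table[table$pattern == p, , drop = FALSE]
    a0 <- sub$auroc[sub$timepoint == "0h"]
    if (length(a0) == 0L) stop("pattern ", p, " missing its 0h cell")
    if (a0 >= threshold) return("prognostic")
    alate <- sub$auroc[sub$timepoint %in% late]
    if (length(alate) && any(alate >= threshold)) return("dynamic")
    "uninformative"
  }, character(1))
  data.frame(pattern = patterns, class = unname(cls), stringsAsFactors = FALSE)
}

#' Scale and center a pattern matrix
#'
#' Each pattern row is centered to mean 0 and scaled to SD 1 (denominator
#' `n - 1`). Zero-variance rows become all zeros with a warning.
#'
#' @param P pattern matrix (patterns x samples).
#' @return scaled matrix of the same shape.
#' @export
scale_patterns <- function(P) {
  if (ncol(P) < 2L) stop("need at least 2 samples to scale")
  mu <- rowMeans(P)
  sdv <- apply(P, 1, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning("zero-variance pattern row(s): ",
            paste(rownames(P)[zero], collapse = ", "))
    sdv[zero] <- 1
  }
  out <- (P - mu) / sdv
  out[zero, ] <- 0
  out
}

stratified_split <- function(y, train_frac = 0.7) {
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(train_frac * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Random-forest importance of patterns for 28-day mortality
#'
#' For each of `n_resplits` resplits: a stratified 70/30 train/test split;
#' on the training portion, repeated stratified k-fold cross-validation
#' (`folds` folds x `repeats` repeats) of a random-forest classifier, with
#' impurity (Gini) importances recorded for every fold model. Importances
#' are averaged over all folds, repeats and resplits. A forest refit on each
#' full training portion also yields a held-out test AUROC per resplit.
#'
#' @param P0 subjects x patterns feature matrix (scaled and centered; see
#'   [scale_patterns()] applied to its transpose).
#' @param labels binary outcome per subject (`TRUE`/`"died"` = positive).
#' @param seed integer; resplit `r` uses `seed + r`.
#' @param n_resplits,folds,repeats resampling configuration (defaults
#'   10/10/10, i.e. the mirrored study configuration).
#' @param ntree trees per forest (default 500).
#' @return data.frame (class `ImportanceTable`) with `pattern`,
#'   `mean_importance`, `sd_importance`, `rank`; attributes `n_resplits`
#'   and `test_auroc` (held-out AUROC per resplit).
#' @export
rf_importance_pipeline <- function(P0, labels, seed = 1L, n_resplits = 10L,
                                   folds = 10L, repeats = 10L, ntree = 500L) {
  y <- as_binary_labels(labels)
  if (nrow(P0) != length(y)) stop("P0 rows must match labels")
  if (nrow(P0) < 20L) stop("need at least 20 subjects")
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  yf <- factor(ifelse(y, "died", "survived"), levels = c("survived", "died"))
  imp <- matrix(NA_real_, nrow = 0, ncol = ncol(P0))
  test_auroc <- numeric(n_resplits)
  for (r in seq_len(n_resplits)) {
    set.seed(seed + r)
    tr <- stratified_split(y, 0.7)
    Xtr <- P0[tr, , drop = FALSE]; ytr <- yf[tr]
    for (rep in seq_len(repeats)) {
      fold <- stratified_folds(ytr, folds)
      for (f in seq_len(folds)) {
        fit <- randomForest::randomForest(Xtr[fold != f, , drop = FALSE],
                                          ytr[fold != f], ntree = ntree)
        imp <- rbind(imp, as.numeric(randomForest::importance(fit)[, 1]))
      }
    }
    full <- randomForest::randomForest(Xtr, ytr, ntree = ntree)
    prob <- stats::predict(full, P0[!tr, , drop = FALSE], type = "prob")[, "died"]
    test_auroc[r] <- auroc(prob, y[!tr])
  }
  mean_imp <- colMeans(imp)
  out <- data.frame(pattern = colnames(P0),
                    mean_importance = mean_imp,
                    sd_importance = apply(imp, 2, stats::sd),
                    rank = rank(-mean_imp, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(out, "n_resplits") <- n_resplits
  attr(out, "test_auroc") <- test_auroc
  class(out) <- c("ImportanceTable", "data.frame")
  out
}

#' Additive AUROC over an importance-ordered pattern prefix
#'
#' Starting from the most important pattern and adding one pattern at a
#' time, reports the held-out random-forest AUROC of each prefix under the
#' same stratified 70/30 resplit scheme as [rf_importance_pipeline()].
#'
#' @param P0 subjects x patterns feature matrix.
#' @param labels binary outcome per subject.
#' @param ordered_patterns character vector of pattern names (most important
#'   first), a subset of `colnames(P0)`.
#' @param seed integer; resplit `r` uses `seed + r`.
#' @param n_resplits resplits (default 10).
#' @param ntree trees per forest.
#' @return data.frame with `n_patterns`, `pattern_added`, `mean_auroc`,
#'   `sd_auroc`.
#' @export
additive_auroc <- function(P0, labels, ordered_patterns, seed = 1L,
                           n_resplits = 10L, ntree = 500L) {
  if (length(ordered_patterns) == 0L) stop("ordering is empty")
  unknown <- setdiff(ordered_patterns, colnames(P0))
  if (length(unknown))
    stop("unknown pattern(s) in ordering: ", paste(unknown, collapse = ", "))
  y <- as_binary_labels(labels)
  yf <- factor(ifelse(y, "died", "survived"), levels = c("survived", "died"))
  rows <- list()
  for (m in seq_along(ordered_patterns)) {
    feats <- ordered_patterns[seq_len(m)]
    aucs <- numeric(n_resplits)
    for (r in seq_len(n_resplits)) {
      set.seed(seed + r)
      tr <- stratified_split(y, 0.7)
      fit <- randomForest::randomForest(P0[tr, feats, drop = FALSE], yf[tr],
                                        ntree = ntree)
      prob <- stats::predict(fit, P0[!tr, feats, drop = FALSE],
                             type = "prob")[, "died"]
      aucs[r] <- auroc(prob, y[!tr])
    }
    rows[[m]] <- data.frame(n_patterns = m, pattern_added = ordered_patterns[m],
                            mean_auroc = mean(aucs), sd_auroc = stats::sd(aucs),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Univariate odds ratios of scaled pattern values for mortality
#'
#' One logistic fit per pattern on its scaled values; the coefficient is
#' exponentiated to an odds ratio per 1 SD with a 95% Wald interval
#' `exp(coef +/- 1.96 SE)`.
#'
#' @param P_scaled subjects x patterns matrix of scaled values (or a scaled
#'   pattern matrix patterns x subjects, which is transposed).
#' @param labels binary outcome per subject.
#' @return data.frame (class `OddsRatioTable`) with `pattern`, `or`,
#'   `ci_low`, `ci_high`, `converged`.
#' @export
pattern_odds_ratios <- function(P_scaled, labels) {
  y <- as_binary_labels(labels)
  X <- if (nrow(P_scaled) == length(y)) P_scaled else t(P_scaled)
  if (nrow(X) != length(y)) stop("dimensions do not match labels")
  rows <- lapply(seq_len(ncol(X)), function(k) {
    fit <- suppressWarnings(stats::glm(y ~ x, data = data.frame(y = y, x = X[, k]),
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    b <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    data.frame(pattern = colnames(X)[k] %||% paste0("P", k),
               or = exp(b), ci_low = exp(b - 1.96 * se),
               ci_high = exp(b + 1.96 * se), converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("OddsRatioTable", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Welch t-tests per gene with Benjamini-Hochberg adjustment
#'
#' Vectorized unequal-variance two-sample t statistic with
#' Welch-Satterthwaite degrees of freedom and two-sided p, adjusted across
#' all tested genes by the Benjamini-Hochberg step-up procedure.
#' Degenerate genes (zero variance in both groups) get `t = 0, p = 1` when
#' the means are equal, and `p = 0` flagged `degenerate` otherwise.
#'
#' @param expr an [expression_matrix()] or matrix (genes x samples).
#' @param group_a,group_b sample ID vectors (at least 2 each).
#' @return data.frame with `gene`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `p_adj`, `degenerate`.
#' @export
welch_bh_diffexp <- function(expr, group_a, group_b) {
  V <- as_values(expr)
  bad <- setdiff(c(group_a, group_b), colnames(V))
  if (length(bad)) stop("unknown sample IDs: ", paste(bad, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least 2 samples per group")
  Xa <- V[, group_a, drop = FALSE]; Xb <- V[, group_b, drop = FALSE]
  na <- ncol(Xa); nb <- ncol(Xb)
  ma <- rowMeans(Xa); mb <- rowMeans(Xb)
  va <- rowSums((Xa - ma)^2) / (na - 1)
  vb <- rowSums((Xb - mb)^2) / (nb - 1)
  sa <- va / na; sb <- vb / nb
  se2 <- sa + sb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  t[degenerate] <- 0
  df[degenerate] <- NA_real_
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  out <- data.frame(gene = rownames(V), mean_a = ma, mean_b = mb, t = t,
                    df = df, p = p, p_adj = stats::p.adjust(p, "BH"),
                    degenerate = degenerate, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Spearman correlation of patterns with covariates
#'
#' Pairwise-complete Spearman rho for every (pattern, covariate) pair, with
#' a two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Constant vectors give `NA`.
#'
#' @param P pattern matrix (patterns x samples).
#' @param covariates data.frame or matrix of numeric covariates, one row per
#'   sample in the column order of `P` (or with rownames matching sample
#'   IDs).
#' @param min_n minimum pairwise-complete observations (default 5); pairs
#'   below it are reported `NA`.
#' @return list with matrices `rho`, `p`, and `n` (patterns x covariates).
#' @export
correlate_patterns <- function(P, covariates, min_n = 5L) {
  CV <- as.matrix(covariates)
  if (!is.null(rownames(CV)) && all(colnames(P) %in% rownames(CV))) {
    CV <- CV[colnames(P), , drop = FALSE]
  } else if (nrow(CV) != ncol(P)) {
    stop("covariates must match the samples of P")
  }
  K <- nrow(P); M <- ncol(CV)
  rho <- p <- n <- matrix(NA_real_, K, M, dimnames = list(rownames(P), colnames(CV)))
  for (i in seq_len(K)) {
    for (j in seq_len(M)) {
      x <- P[i, ]; yv <- CV[, j]
      ok <- is.finite(x) & is.finite(yv)
      n[i, j] <- sum(ok)
      if (n[i, j] < min_n) next
      if (stats::sd(x[ok]) == 0 || stats::sd(yv[ok]) == 0) next
      r <- stats::cor(x[ok], yv[ok], method = "spearman")
      rho[i, j] <- r
      nn <- n[i, j]
      if (abs(r) >= 1) {
        p[i, j] <- 0
      } else {
        tt <- r * sqrt((nn - 2) / (1 - r^2))
        p[i, j] <- 2 * stats::pt(-abs(tt), nn - 2)
      }
    }
  }
  list(rho = rho, p = p, n = n)
}
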