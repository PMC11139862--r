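#' Configuration for a synthetic longitudinal sepsis cohort
#'
#' Defines the shape of a simulated cohort: healthy donors plus sepsis
#' subjects sampled at up to eight timepoints (enrolment through 12 months),
#' with 28-day outcome counts, death/dropout missingness, and a known
#' non-negative factorization generating the expression.
#'
#' Defaults mirror the study cohort shape this package was built around:
#' 120 sepsis subjects with outcome counts (63 survived, 54 died, 3 unknown)
#' plus 42 healthy donors.
#'
#' @param n_sepsis_subjects number of sepsis subjects.
#' @param n_healthy number of healthy donors (one sample each).
#' @param outcome_counts named integer vector `c(survived=, died=, unknown=)`
#'   summing to `n_sepsis_subjects`.
#' @param timepoints ordered subset of the canonical labels
#'   `names(canonical_timepoints())`.
#' @param n_genes number of genes.
#' @param K_true number of ground-truth patterns.
#' @param pattern_classes character vector of length `K_true` over
#'   `"prognostic"`, `"dynamic"`, `"null"`. Default alternates so that a
#'   third of patterns (rounded) are prognostic, a third dynamic, rest null.
#' @param effect_size standardized mean difference (in units of the
#'   between-subject SD) separating non-survivors from survivors: applied at
#'   enrolment for prognostic patterns and as the acute elevation whose decay
#'   separates the groups later for dynamic patterns.
#' @param tau recovery time constant in hours for survivor decay toward the
#'   healthy mean; recycled over patterns.
#' @param subject_sd between-subject SD of pattern weights (weight units).
#' @param sparsity fraction of genes with zero amplitude in each pattern.
#' @param noise list: `list(type = "lognormal", sigma = 0.2)` for
#'   multiplicative log-normal noise on TPM, `list(type = "poisson",
#'   depth = d)` for Poisson counts at scale `d`, or `list(type = "none")`.
#' @param retention named per-timepoint retention probabilities (survivors);
#'   non-survivors use the same probabilities through 72 h and are truncated
#'   after. Enrolment (0h) is always retained.
#' @param seed integer RNG seed.
#' @return a `SyntheticCohortConfig` list.
#' @export
cohort_config <- function(n_sepsis_subjects = 120L,
                          n_healthy = 42L,
                          outcome_counts = c(survived = 63L, died = 54L, unknown = 3L),
                          timepoints = names(canonical_timepoints()),
                          n_genes = 2000L,
                          K_true = 6L,
                          pattern_classes = NULL,
                          effect_size = c(prognostic = 1.5, dynamic = 2.0),
                          tau = 72,
                          subject_sd = 0.15,
                          sparsity = 0.7,
                          noise = list(type = "lognormal", sigma = 0.2),
                          retention = c("0h" = 1, "6h" = 0.85, "24h" = 0.8,
                                        "48h" = 0.7, "72h" = 0.6, "28d" = 0.6,
                                        "6m" = 0.55, "12m" = 0.5),
                          seed = 1L) {
  canon <- names(canonical_timepoints())
  if (!all(timepoints %in% canon))
    stop("timepoints must be a subset of: ", paste(canon, collapse = ", "))
  timepoints <- canon[canon %in% timepoints]  # canonical order
  if (length(outcome_counts) != 3L ||
      !all(c("survived", "died", "unknown") %in% names(outcome_counts)))
    stop("outcome_counts must be named (survived, died, unknown)")
  if (sum(outcome_counts) != n_sepsis_subjects)
    stop("outcome counts (", sum(outcome_counts),
         ") do not sum to n_sepsis_subjects (", n_sepsis_subjects, ")")
  if (K_true < 1L) stop("K_true must be >= 1")
  if (K_true > n_genes) stop("K_true (", K_true, ") exceeds n_genes (", n_genes, ")")
  if (is.null(pattern_classes)) {
    n_prog <- max(1L, round(K_true / 3))
    n_dyn <- if (K_true >= 2L) max(1L, round(K_true / 3)) else 0L
    pattern_classes <- rep("null", K_true)
    pattern_classes[seq_len(n_prog)] <- "prognostic"
    if (n_dyn > 0L) pattern_classes[n_prog + seq_len(n_dyn)] <- "dynamic"
  }
  if (length(pattern_classes) != K_true ||
      !all(pattern_classes %in% c("prognostic", "dynamic", "null")))
    stop("pattern_classes must be length K_true over prognostic/dynamic/null")
  if (!noise$type %in% c("lognormal", "poisson", "none"))
    stop("noise$type must be lognormal, poisson or none")
  structure(list(
    n_sepsis_subjects = as.integer(n_sepsis_subjects),
    n_healthy = as.integer(n_healthy),
    outcome_counts = outcome_counts,
    timepoints = timepoints,
    n_genes = as.integer(n_genes),
    K_true = as.integer(K_true),
    pattern_classes = pattern_classes,
    effect_size = effect_size,
    tau = rep_len(tau, K_true),
    subject_sd = subject_sd,
    sparsity = sparsity,
    noise = noise,
    retention = retention,
    seed = as.integer(seed)
  ), class = "SyntheticCohortConfig")
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Draws a non-negative amplitude matrix `A_true` (genes x K) and builds
#' per-sample pattern weights `P_true` (K x samples) from outcome-linked
#' temporal dynamics: survivor weights decay exponentially toward the
#' healthy-donor mean, `w(t) = w_healthy + (w_acute - w_healthy) *
#' exp(-t / tau)`, while non-survivor weights stay at their enrolment level
#' and non-survivors contribute no samples after 72 h. Expression is
#' `A_true %*% P_true` perturbed by the configured noise model.
#'
#' @param config a [cohort_config()].
#' @return list with elements `expression` (an [expression_matrix()], raw
#'   TPM scale), `metadata` (per-sample data.frame, one row per expression
#'   column) and `truth` (a `GroundTruth` list with `A_true`, `P_true`,
#'   `outcome_effects`, `noise_model`, `seed`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  set.seed(config$seed)
  K <- config$K_true
  G <- config$n_genes
  gene_ids <- sprintf("gene_%04d", seq_len(G))
  pat_ids <- sprintf("T%02d", seq_len(K))

  # amplitude: exponential entries with per-pattern sparsity masking
  A <- matrix(stats::rexp(G * K), nrow = G,
              dimnames = list(gene_ids, pat_ids))
  mask <- matrix(stats::runif(G * K) >= config$sparsity, nrow = G)
  A <- A * mask
  # keep every pattern identifiable: at least one nonzero gene
  for (k in seq_len(K)) if (all(A[, k] == 0)) A[sample.int(G, 1L), k] <- stats::rexp(1)

  w_healthy <- stats::runif(K, 0.5, 1.5)
  sdw <- config$subject_sd
  eff <- config$effect_size
  # group-level acute elevation above healthy, per pattern and outcome
  elev_surv <- ifelse(config$pattern_classes == "prognostic", 2 * sdw,
               ifelse(config$pattern_classes == "dynamic",
                      eff[["dynamic"]] * sdw, 0))
  elev_died <- elev_surv +
    ifelse(config$pattern_classes == "prognostic", eff[["prognostic"]] * sdw, 0)

  # subjects
  oc <- config$outcome_counts
  outcomes <- c(rep("survived", oc[["survived"]]), rep("died", oc[["died"]]),
                rep("unknown", oc[["unknown"]]))
  outcomes <- sample(outcomes)  # interleave so IDs carry no outcome order
  n_sep <- config$n_sepsis_subjects
  subj_ids <- sprintf("sepsis_%03d", seq_len(n_sep))
  healthy_ids <- if (config$n_healthy > 0) sprintf("healthy_%03d", seq_len(config$n_healthy)) else character()

  tp <- canonical_timepoints()[config$timepoints]
  ret <- config$retention
  samples <- list()
  pcols <- list()

  add_sample <- function(sid, subj, tpl, grp, out, age, sex, w) {
    samples[[length(samples) + 1L]] <<- data.frame(
      sample_id = sid, subject_id = subj, timepoint = tpl,
      hours = unname(canonical_timepoints()[tpl]), group = grp, outcome = out,
      age = age, sex = sex, stringsAsFactors = FALSE)
    pcols[[length(pcols) + 1L]] <<- w
  }

  for (i in seq_len(config$n_healthy)) {
    age <- round(stats::runif(1, 20, 70))
    sex <- sample(c("F", "M"), 1L)
    w <- pmax(w_healthy + stats::rnorm(K, 0, sdw), 0)
    add_sample(paste0(healthy_ids[i], "_0h"), healthy_ids[i], "0h",
               "healthy", "not_applicable", age, sex, w)
  }
  for (i in seq_len(n_sep)) {
    out <- outcomes[i]
    age <- round(stats::runif(1, 18, 85))
    sex <- sample(c("F", "M"), 1L)
    elev <- if (out == "died") elev_died else elev_surv
    w_acute <- pmax(w_healthy + elev + stats::rnorm(K, 0, sdw), 0)
    for (tpl in config$timepoints) {
      h <- unname(tp[tpl])
      if (out == "died" && h > 72) next
      keep <- tpl == "0h" || stats::runif(1) < ret[[tpl]]
      if (!keep) next
      w <- if (out == "died") w_acute
           else w_healthy + (w_acute - w_healthy) * exp(-h / config$tau)
      add_sample(paste0(subj_ids[i], "_", tpl), subj_ids[i], tpl,
                 "sepsis", out, age, sex, pmax(w, 0))
    }
  }

  meta <- do.call(rbind, samples)
  P <- do.call(cbind, pcols)
  dimnames(P) <- list(pat_ids, meta$sample_id)
  D <- A %*% P
  noise <- config$noise
  if (noise$type == "lognormal" && noise$sigma > 0) {
    D <- D * exp(matrix(stats::rnorm(length(D), -noise$sigma^2 / 2, noise$sigma),
                        nrow = nrow(D)))
  } else if (noise$type == "poisson") {
    depth <- if (is.null(noise$depth)) 1 else noise$depth
    D <- matrix(stats::rpois(length(D), D * depth), nrow = nrow(D),
                dimnames = dimnames(D)) / depth
  }

  outcome_effects <- lapply(seq_len(K), function(k) list(
    class = config$pattern_classes[k],
    effect_size = if (config$pattern_classes[k] == "null") 0
                  else unname(eff[[config$pattern_classes[k]]])))
  names(outcome_effects) <- pat_ids

  truth <- structure(list(A_true = A, P_true = P,
                          w_healthy = stats::setNames(w_healthy, pat_ids),
                          outcome_effects = outcome_effects,
                          noise_model = noise, seed = config$seed,
                          config = config),
                     class = "GroundTruth")
  list(expression = expression_matrix(D, "raw_tpm"),
       metadata = validate_metadata(meta),
       truth = truth)
}

#' Generate an annotated single-cell-like projection target
#'
#' Builds a toy expression matrix whose cells load on known ground-truth
#' patterns: each cell's expected expression is
#' `A_true %*% (type_loading + jitter)`. Useful as a projection fixture for
#' cell-type enrichment analyses.
#'
#' @param truth a `GroundTruth` from [generate_cohort()].
#' @param cell_type_loadings named list; each element is either a full
#'   length-`K_true` non-negative weight vector, or a named numeric vector
#'   whose names are pattern indices (e.g. `c("3" = 1)`).
#' @param n_cells_per_type count (recycled over types).
#' @param jitter_sd SD of the per-cell weight jitter (0 = identical cells).
#' @param seed integer seed.
#' @return list with `expression` (an [expression_matrix()]) and
#'   `annotation` (data.frame with `cell_id`, `cell_type`).
#' @export
generate_target_cells <- function(truth, cell_type_loadings, n_cells_per_type,
                                  jitter_sd = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  K <- ncol(truth$A_true)
  set.seed(seed)
  loadings <- lapply(names(cell_type_loadings), function(ct) {
    v <- cell_type_loadings[[ct]]
    if (length(v) == K && is.null(names(v))) {
      w <- as.numeric(v)
    } else {
      idx <- suppressWarnings(as.integer(names(v)))
      if (anyNA(idx) || any(idx < 1L) || any(idx > K))
        stop("unknown pattern index in loading for cell type '", ct, "'")
      w <- numeric(K)
      w[idx] <- as.numeric(v)
    }
    if (any(w < 0)) stop("loading for cell type '", ct, "' has negative weights")
    w
  })
  names(loadings) <- names(cell_type_loadings)
  n_per <- rep_len(as.integer(n_cells_per_type), length(loadings))

  cols <- list(); ann <- list()
  for (j in seq_along(loadings)) {
    ct <- names(loadings)[j]
    for (c in seq_len(n_per[j])) {
      w <- pmax(loadings[[j]] + stats::rnorm(K, 0, jitter_sd), 0)
      cols[[length(cols) + 1L]] <- truth$A_true %*% w
      ann[[length(ann) + 1L]] <- data.frame(
        cell_id = sprintf("%s_cell_%03d", ct, c), cell_type = ct,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cols) == 0L) {
    values <- matrix(numeric(0), nrow = nrow(truth$A_true), ncol = 0,
                     dimnames = list(rownames(truth$A_true), NULL))
    annotation <- data.frame(cell_id = character(), cell_type = character(),
                             stringsAsFactors = FALSE)
  } else {
    annotation <- do.call(rbind, ann)
    values <- do.call(cbind, cols)
    dimnames(values) <- list(rownames(truth$A_true), annotation$cell_id)
  }
  list(expression = expression_matrix(values, "raw_tpm"),
       annotation = annotation)
}

#' Generate ground-truth and control gene sets
#'
#' One "true" set per pattern containing the `top_n` genes by ground-truth
#' amplitude (ties broken by gene ID), plus uniformly drawn control sets of
#' the same size. Default `top_n = 20` matches the top-20 signature-gene
#' convention used throughout the enrichment analyses.
#'
#' @param truth a `GroundTruth`.
#' @param top_n genes per set.
#' @param n_random_controls number of random control sets.
#' @param seed integer seed for the control draws.
#' @return named list of character vectors (a gene-set collection); the
#'   `description` attribute carries per-set descriptions.
#' @export
generate_gene_sets <- function(truth, top_n = 20L, n_random_controls = 0L,
                               seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (top_n <= 0) stop("top_n must be positive")
  G <- nrow(truth$A_true)
  if (top_n > G) stop("top_n (", top_n, ") exceeds number of genes (", G, ")")
  set.seed(seed)
  sets <- list(); desc <- character()
  genes <- rownames(truth$A_true)
  for (k in seq_len(ncol(truth$A_true))) {
    ord <- order(-truth$A_true[, k], genes)
    nm <- paste0("true_", colnames(truth$A_true)[k])
    sets[[nm]] <- genes[ord[seq_len(top_n)]]
    desc[nm] <- paste0("top-", top_n, " amplitude genes of pattern ",
                       colnames(truth$A_true)[k])
  }
  for (r in seq_len(n_random_controls)) {
    nm <- sprintf("control_%02d", r)
    sets[[nm]] <- sample(genes, top_n)
    desc[nm] <- "uniform random control set"
  }
  attr(sets, "description") <- desc
  sets
}
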