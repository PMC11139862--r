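# Small cohort configurations used across test files.

tiny_cohort_config <- function(seed = 1, noise = list(type = "none"), ...) {
  cohort_config(
    n_sepsis_subjects = 12L, n_healthy = 4L,
    outcome_counts = c(survived = 6L, died = 5L, unknown = 1L),
    n_genes = 120L, K_true = 3L, seed = seed, noise = noise, ...)
}

# metadata table with the study's printed outcome composition
study_shape_metadata <- function() {
  subj <- c(sprintf("sepsis_%03d", 1:120), sprintf("healthy_%03d", 1:42))
  outcome <- c(rep("survived", 63), rep("died", 54), rep("unknown", 3),
               rep("not_applicable", 42))
  data.frame(
    sample_id = paste0(subj, "_0h"), subject_id = subj, timepoint = "0h",
    group = c(rep("sepsis", 120), rep("healthy", 42)), outcome = outcome,
    age = 40, sex = "F", stringsAsFactors = FALSE)
}

random_expression <- function(genes = 10, samples = 6, seed = 1) {
  set.seed(seed)
  V <- matrix(stats::rexp(genes * samples), genes,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  expression_matrix(V, "raw_tpm")
}

# exhaustive two-sample KS oracle: enumerate all label assignments
ks_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  ks_D <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  D_obs <- ks_D(x, y)
  combos <- utils::combn(n + m, n)
  Ds <- apply(combos, 2, function(idx) ks_D(pooled[idx], pooled[-idx]))
  list(D = D_obs, p = mean(Ds >= D_obs - 1e-12))
}
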