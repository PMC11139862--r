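test_that("default cohort mirrors the study composition", {
  cfg <- cohort_config(seed = 3)
  ch <- generate_cohort(cfg)
  m <- ch$metadata
  expect_equal(sum(m$group == "healthy"), 42)
  sep <- m[m$group == "sepsis", ]
  by_subj <- tapply(sep$outcome, sep$subject_id, function(x) x[1])
  expect_equal(unname(table(factor(by_subj, c("survived", "died", "unknown")))),
               c(63L, 54L, 3L), ignore_attr = TRUE)
  expect_equal(length(unique(sep$subject_id)), 120)
  # one metadata row per expression column, in order
  expect_identical(m$sample_id, colnames(ch$expression$values))
})

test_that("noise-free expression equals the ground-truth product exactly", {
  ch <- generate_cohort(tiny_cohort_config(seed = 5))
  expect_identical(ch$expression$values, ch$truth$A_true %*% ch$truth$P_true)
  expect_true(all(ch$truth$A_true >= 0))
  expect_true(all(ch$truth$P_true >= 0))
})

test_that("generation is a pure function of (config, seed)", {
  a <- generate_cohort(tiny_cohort_config(seed = 9,
                                          noise = list(type = "lognormal", sigma = 0.2)))
  b <- generate_cohort(tiny_cohort_config(seed = 9,
                                          noise = list(type = "lognormal", sigma = 0.2)))
  expect_identical(a$expression, b$expression)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(tiny_cohort_config(seed = 10,
                                          noise = list(type = "lognormal", sigma = 0.2)))
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("non-survivors have no samples after 72 h and survivors decay toward healthy", {
  ch <- generate_cohort(cohort_config(seed = 2))
  m <- ch$metadata
  expect_true(all(m$hours[m$outcome == "died"] <= 72))
  # survivor weights decay toward the healthy mean for elevated patterns
  P <- ch$truth$P_true
  surv <- m$outcome == "survived"
  late <- surv & m$hours >= 4380
  early <- surv & m$hours == 0
  wh <- ch$truth$w_healthy
  k_elev <- which(vapply(ch$truth$outcome_effects,
                         function(e) e$class != "null", logical(1)))[1]
  expect_lt(abs(mean(P[k_elev, m$sample_id[late]]) - wh[k_elev]),
            abs(mean(P[k_elev, m$sample_id[early]]) - wh[k_elev]))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_sepsis_subjects = 10,
                             outcome_counts = c(survived = 5, died = 4, unknown = 2)),
               "do not sum")
  expect_error(cohort_config(n_genes = 4, K_true = 5), "exceeds n_genes")
  expect_error(cohort_config(timepoints = c("0h", "3d")), "subset")
})

test_that("target cells load on the requested patterns", {
  ch <- generate_cohort(tiny_cohort_config(seed = 4))
  tc <- generate_target_cells(ch$truth,
                              list(tA = c("1" = 1), tB = c("3" = 1)),
                              n_cells_per_type = 5, jitter_sd = 0, seed = 2)
  expect_equal(ncol(tc$expression$values), 10)
  expect_identical(tc$annotation$cell_id, colnames(tc$expression$values))
  # jitter 0 -> all cells of a type identical
  va <- tc$expression$values[, tc$annotation$cell_type == "tA", drop = FALSE]
  expect_true(all(va == va[, 1]))
  # oracle: direct least squares on noise-free cells recovers the loading
  w <- qr.solve(ch$truth$A_true, va[, 1])
  expect_equal(unname(w), c(1, 0, 0), tolerance = 1e-8)
  # empty case
  e <- generate_target_cells(ch$truth, list(tA = c("1" = 1)), 0)
  expect_equal(ncol(e$expression$values), 0)
  expect_equal(nrow(e$annotation), 0)
  # unknown pattern index
  expect_error(generate_target_cells(ch$truth, list(tA = c("9" = 1)), 1),
               "unknown pattern index")
})

test_that("gene sets are the top amplitude genes plus reproducible controls", {
  ch <- generate_cohort(tiny_cohort_config(seed = 8))
  sets <- generate_gene_sets(ch$truth, top_n = 20, n_random_controls = 3, seed = 6)
  expect_length(sets, 3 + 3)
  for (k in 1:3) {
    s <- sets[[paste0("true_T0", k)]]
    expect_length(unique(s), 20)
    expect_true(all(s %in% rownames(ch$truth$A_true)))
    # cross-module consistency: equals the top-20 of the amplitude ranking
    ranked <- rank_genes_by_amplitude(list(A = ch$truth$A_true), k)
    expect_setequal(s, ranked$gene[1:20])
  }
  sets2 <- generate_gene_sets(ch$truth, top_n = 20, n_random_controls = 3, seed = 6)
  expect_identical(sets, sets2)
  # saturation: K_true = 1, top_n = n_genes
  ch1 <- generate_cohort(cohort_config(n_sepsis_subjects = 6, n_healthy = 2,
                                       outcome_counts = c(survived = 3, died = 2, unknown = 1),
                                       n_genes = 15, K_true = 1,
                                       pattern_classes = "prognostic", seed = 1))
  s1 <- generate_gene_sets(ch1$truth, top_n = 15)
  expect_setequal(s1[[1]], rownames(ch1$truth$A_true))
  expect_error(generate_gene_sets(ch$truth, top_n = 0), "positive")
})
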