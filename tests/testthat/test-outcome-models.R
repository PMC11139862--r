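test_that("the known-outcome filter retains the expected subjects", {
  meta <- validate_metadata(study_shape_metadata())
  kept <- filter_known_outcome(meta)
  expect_equal(attr(kept, "n_subjects"), 117)
  expect_false(any(kept$outcome == "unknown"))
  expect_false(any(kept$group == "healthy"))
  # conservation: retained + removed = input subjects
  expect_equal(attr(kept, "n_subjects") +
                 length(unique(meta$subject_id[!meta$sample_id %in% kept$sample_id])),
               length(unique(meta$subject_id)))
  # no unknowns -> unchanged rows
  kept2 <- filter_known_outcome(kept)
  expect_equal(nrow(kept2), nrow(kept))
  all_unknown <- meta[meta$outcome == "unknown", ]
  expect_error(filter_known_outcome(all_unknown), "no subjects")
})

test_that("AUROC follows the Mann-Whitney rank formulation", {
  set.seed(41)
  for (i in 1:5) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    s <- c(rnorm(n1, 1), rnorm(n0))
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    w <- wilcox.test(s[y], s[!y])$statistic
    expect_equal(auroc(s, y), unname(w) / (n1 * n0), tolerance = 1e-12)
  }
  expect_equal(auroc(c(5, 4, 3, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("binormal simulation reproduces the closed-form AUROC", {
  set.seed(42)
  scores <- c(rnorm(500, 1), rnorm(500, 0))
  y <- rep(c(TRUE, FALSE), each = 500)
  expect_lt(abs(auroc(scores, y) - pnorm(1 / sqrt(2))), 0.03)
})

test_that("logistic AUROC handles constant and perfectly separating patterns", {
  meta <- validate_metadata(study_shape_metadata())
  ids <- meta$sample_id
  set.seed(43)
  P <- rbind(const = rep(1, length(ids)),
             perfect = ifelse(meta$outcome == "died", 1, 0) + 0,
             noise = rnorm(length(ids)))
  colnames(P) <- ids
  # constant pattern with constant covariates -> AUROC 0.5
  r1 <- pattern_logistic_auroc(P, meta, 1, "0h", covariates = character())
  expect_equal(r1$auroc, 0.5)
  # perfect separation: AUROC 1, flagged non-converged
  r2 <- suppressWarnings(pattern_logistic_auroc(P, meta, 2, "0h",
                                                covariates = character()))
  expect_equal(r2$auroc, 1.0)
  expect_equal(r2$n_died, 54)
  expect_equal(r2$n_survived, 63)
})

test_that("patterns are classified prognostic, dynamic or uninformative", {
  mk <- function(p, a) data.frame(pattern = p,
                                  timepoint = c("0h", "6h", "24h", "48h", "72h"),
                                  auroc = a, stringsAsFactors = FALSE)
  tab <- rbind(mk("A", c(0.9, 0.9, 0.9, 0.9, 0.9)),
               mk("B", c(0.55, 0.60, 0.65, 0.75, 0.80)),
               mk("C", rep(0.5, 5)))
  cls <- classify_patterns(tab, threshold = 0.7)
  expect_identical(cls$class, c("prognostic", "dynamic", "uninformative"))
  # a mid-acute peak that misses 0h and 48h+ is uninformative
  tab2 <- mk("D", c(0.55, 0.8, 0.8, 0.6, 0.6))
  expect_identical(classify_patterns(tab2, 0.7)$class, "uninformative")
  expect_error(classify_patterns(tab[tab$timepoint != "0h", ], 0.7), "0h")
})

test_that("pattern scaling centers rows and is idempotent", {
  P <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(S <- scale_patterns(P), "zero-variance")
  expect_equal(unname(S["a", ]), c(-1, 0, 1))
  expect_equal(unname(S["b", ]), c(0, 0, 0))
  P2 <- matrix(rnorm(40), 4)
  S2 <- scale_patterns(P2)
  expect_equal(scale_patterns(S2), S2, tolerance = 1e-12)
})

test_that("random-forest importance finds the single signal pattern", {
  set.seed(44)
  n <- 200
  y <- rep(c("died", "survived"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, sprintf("P%02d", 1:10)))
  X[, 4] <- X[, 4] + ifelse(y == "died", 2, 0)   # standardized effect 2.0
  X <- scale(X)
  tab <- rf_importance_pipeline(X, y, seed = 3, n_resplits = 4, folds = 5,
                                repeats = 2, ntree = 200)
  expect_equal(tab$pattern[tab$rank == 1], "P04")
  expect_true(all(tab$mean_importance >= 0))
  expect_setequal(tab$rank, 1:10)
  # oracle: univariate AUROC ranks the same pattern first
  uni <- apply(X, 2, function(v) auroc(v, y == "died"))
  expect_equal(names(which.max(uni)), "P04")
  # reproducibility
  tab2 <- rf_importance_pipeline(X, y, seed = 3, n_resplits = 4, folds = 5,
                                 repeats = 2, ntree = 200)
  expect_identical(tab, tab2)
  expect_error(rf_importance_pipeline(X, rep("died", n), seed = 1), "single class")
})

test_that("additive AUROC is high for the signal prefix and stable to noise", {
  set.seed(45)
  n <- 200
  y <- rep(c("died", "survived"), each = n / 2)
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, sprintf("P%02d", 1:6)))
  X[, 1] <- X[, 1] + ifelse(y == "died", 2, 0)
  X <- scale(X)
  add <- additive_auroc(X, y, c("P01", "P02"), seed = 5, n_resplits = 5,
                        ntree = 200)
  expect_equal(nrow(add), 2)
  expect_gte(add$mean_auroc[1], 0.80)
  expect_lt(abs(add$mean_auroc[2] - add$mean_auroc[1]), 0.05)
  one <- additive_auroc(X, y, "P01", seed = 5, n_resplits = 3, ntree = 100)
  expect_equal(nrow(one), 1)
  expect_error(additive_auroc(X, y, c("P01", "nope"), seed = 1), "unknown pattern")
})

test_that("held-out AUROC is near 0.5 under permuted labels", {
  set.seed(46)
  n <- 120
  y <- sample(rep(c("died", "survived"), each = n / 2))
  X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, sprintf("P%02d", 1:8)))
  tab <- rf_importance_pipeline(X, y, seed = 7, n_resplits = 5, folds = 5,
                                repeats = 1, ntree = 200)
  expect_gte(mean(attr(tab, "test_auroc")), 0.40)
  expect_lte(mean(attr(tab, "test_auroc")), 0.60)
})

test_that("odds ratios match the 2x2 closed form and invert with labels", {
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))          # exposed/unexposed
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 10, 10, 20))
  or <- pattern_odds_ratios(matrix(x, ncol = 1, dimnames = list(NULL, "p1")), y)
  expect_equal(or$or, (20 * 20) / (10 * 10), tolerance = 1e-4)
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)
  flipped <- pattern_odds_ratios(matrix(x, ncol = 1,
                                        dimnames = list(NULL, "p1")), !y)
  expect_equal(flipped$or, 1 / or$or, tolerance = 1e-6)
  # null predictor: CI contains 1
  set.seed(47)
  xn <- rnorm(2000); yn <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  orn <- pattern_odds_ratios(matrix(xn, ncol = 1, dimnames = list(NULL, "p")), yn)
  expect_true(orn$ci_low <= 1 && 1 <= orn$ci_high)
})

test_that("Welch t-tests match t.test and BH is monotone above raw p", {
  em <- random_expression(20, 12, seed = 48)
  colnames(em$values) <- c(paste0("a", 1:6), paste0("b", 1:6))
  res <- welch_bh_diffexp(em, paste0("a", 1:6), paste0("b", 1:6))
  for (g in c(1, 7, 20)) {
    tt <- t.test(em$values[g, 1:6], em$values[g, 7:12])
    expect_equal(res$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[g], tt$p.value, tolerance = 1e-10)
    expect_equal(res$df[g], unname(tt$parameter), tolerance = 1e-10)
  }
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-12))
  # identical groups -> t = 0, p = 1
  V <- em$values[, 1:6]
  both <- cbind(V, V); colnames(both) <- c(paste0("a", 1:6), paste0("b", 1:6))
  res0 <- welch_bh_diffexp(both, paste0("a", 1:6), paste0("b", 1:6))
  expect_true(all(res0$t == 0) && all(res0$p == 1))
  # strong shift: closed-form Welch statistic ~ 10 -> tiny p
  set.seed(49)
  sh <- rbind(g1 = c(rnorm(50), rnorm(50, 2)))
  colnames(sh) <- c(paste0("a", 1:50), paste0("b", 1:50))
  resS <- welch_bh_diffexp(sh, paste0("a", 1:50), paste0("b", 1:50))
  expect_lt(resS$p[1], 1e-10)
  # degenerate: zero variance, unequal means
  dg <- rbind(g1 = rep(c(0, 1), each = 3))
  colnames(dg) <- c(paste0("a", 1:3), paste0("b", 1:3))
  resD <- welch_bh_diffexp(dg, paste0("a", 1:3), paste0("b", 1:3))
  expect_true(resD$degenerate[1])
  expect_equal(resD$p[1], 0)
})

test_that("Spearman correlations match the rank-formula oracle", {
  P <- rbind(p1 = c(3.2, 1.1, 4.8, 2.0, 5.5, 0.3))
  colnames(P) <- paste0("s", 1:6)
  cov <- data.frame(up = 2^P[1, ], down = -P[1, ],
                    other = c(2, 9, 4, 4, 1, 7))
  res <- correlate_patterns(P, cov)
  expect_equal(res$rho["p1", "up"], 1)
  expect_equal(res$rho["p1", "down"], -1)
  # oracle: rho = 1 - 6*sum(d^2)/(n(n^2-1)) for untied vectors
  rx <- rank(P[1, ]); ry <- rank(c(2, 9, 4, 4.5, 1, 7))
  cov2 <- data.frame(v = c(2, 9, 4, 4.5, 1, 7))
  d <- rx - ry
  expect_equal(unname(correlate_patterns(P, cov2)$rho[1, 1]),
               1 - 6 * sum(d^2) / (6 * 35), tolerance = 1e-12)
  # constant covariate -> NA; short pairwise-complete -> NA
  cov3 <- data.frame(const = rep(1, 6), short = c(1, 2, NA, NA, NA, NA))
  res3 <- correlate_patterns(P, cov3)
  expect_true(all(is.na(res3$rho[1, ])))
})
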