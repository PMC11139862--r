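pipeline_defaults <- function() {
  list(
    # input paths; all NULL -> simulate a synthetic cohort
    expression = NULL, metadata = NULL, gene_sets = NULL,
    # synthetic cohort
    n_genes = 2000L, K_true = 6L, noise_sigma = 0.2,
    # factorization
    K = 30L, sparsity = NULL, tol = 1e-5, max_iter = 250L, n_restarts = 2L,
    min_detect_frac = 0.05,
    # projection
    projection_method = "ols", min_shared_fraction = 0.5,
    # outcome modeling
    auroc_threshold = 0.7, resplits = 10L, folds = 10L, repeats = 10L,
    ntree = 500L, importance_timepoint = "0h",
    # enrichment
    n_perm = 9999L, iterations = 10000L, set_size = 20L,
    # global
    seed = 1L
  )
}

#' Build a validated pipeline configuration
#'
#' A flat key-value configuration for [run_pipeline()]. Unknown keys are
#' rejected (typo guard), numeric parameters are range checked, and every
#' omitted key takes its documented default. The global `seed` fans out to
#' per-stage seeds by fixed offsets so stages can be rerun independently.
#'
#' @param ... configuration keys; see the source of
#'   `sepsisPatterns:::pipeline_defaults` for the full list and defaults.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  stopifnot(cfg$K >= 1, cfg$K_true >= 1, cfg$n_genes >= cfg$K_true,
            cfg$tol > 0, cfg$max_iter >= 1, cfg$n_restarts >= 1,
            cfg$auroc_threshold > 0.5, cfg$auroc_threshold < 1,
            cfg$resplits >= 1, cfg$folds >= 2, cfg$repeats >= 1,
            cfg$n_perm >= 99, cfg$iterations >= 1, cfg$set_size >= 1,
            cfg$min_shared_fraction >= 0, cfg$min_shared_fraction <= 1,
            cfg$noise_sigma >= 0)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a flat YAML file
#' @param path YAML file with top-level scalar keys only.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' Run the full pattern-analysis pipeline
#'
#' Executes, in order: simulate (when no expression path is configured) ->
#' log transform and gene filter -> non-negative factorization -> AUROC
#' classification of patterns against 28-day mortality -> random-forest
#' importance and additive AUROC -> gene-set rank enrichment with its
#' background model -> trajectory and recovery summaries. Every artifact is
#' written under `out_dir` along with a manifest (seeds, parameters) and a
#' log of stage durations. Reruns with the same configuration produce
#' identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(sprintf("stage %-12s done in %.1f s", name,
                proc.time()[["elapsed"]] - t0))
    out
  }
  say("pipeline seed: ", config$seed)

  # --- simulate or load ------------------------------------------------
  truth <- NULL
  sim <- is.null(config$expression)
  if (sim) {
    cohort <- run_stage("simulate", function() {
      cc <- cohort_config(n_genes = config$n_genes, K_true = config$K_true,
                          noise = list(type = "lognormal",
                                       sigma = config$noise_sigma),
                          seed = config$seed + 1L)
      generate_cohort(cc)
    })
    expr <- cohort$expression
    meta <- cohort$metadata
    truth <- cohort$truth
    write_expression_tsv(expr, file.path(out_dir, "expression.tsv"), digits = 6)
    write_metadata_csv(meta, file.path(out_dir, "metadata.csv"))
    sets <- generate_gene_sets(truth, top_n = config$set_size,
                               n_random_controls = 2L, seed = config$seed + 5L)
    write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
  } else {
    expr <- run_stage("load", function()
      read_expression_tsv(config$expression))
    meta <- read_metadata_csv(config$metadata)
    sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets) else NULL
  }

  # --- transform -------------------------------------------------------
  lg <- run_stage("transform", function()
    filter_genes(log_transform(expr), config$min_detect_frac))

  # --- factorize -------------------------------------------------------
  fit <- run_stage("factorize", function()
    fit_nmf(lg, K = config$K, sparsity = config$sparsity,
            seed = config$seed + 2L, tol = config$tol,
            max_iter = config$max_iter, n_restarts = config$n_restarts))
  write_factorization(fit, file.path(out_dir, "factorization"))
  say(sprintf("relative reconstruction error: %.4f",
              reconstruction_error(fit, lg)))

  # --- classify --------------------------------------------------------
  cls <- run_stage("classify", function() {
    at <- auroc_table(fit$P, meta)
    list(auroc = at, classes = classify_patterns(at, config$auroc_threshold))
  })
  utils::write.table(cls$auroc, file.path(out_dir, "auroc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cls$classes, file.path(out_dir, "pattern_classes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- importance ------------------------------------------------------
  imp <- run_stage("importance", function() {
    m0 <- filter_known_outcome(meta)
    m0 <- m0[m0$timepoint == config$importance_timepoint, , drop = FALSE]
    P0 <- t(scale_patterns(fit$P)[, m0$sample_id, drop = FALSE])
    rownames(P0) <- m0$subject_id
    tab <- rf_importance_pipeline(P0, m0$outcome, seed = config$seed + 3L,
                                  n_resplits = config$resplits,
                                  folds = config$folds,
                                  repeats = config$repeats,
                                  ntree = config$ntree)
    top <- tab$pattern[order(tab$rank)][seq_len(min(5L, nrow(tab)))]
    add <- additive_auroc(P0, m0$outcome, top, seed = config$seed + 3L,
                          n_resplits = config$resplits, ntree = config$ntree)
    ors <- pattern_odds_ratios(P0[, top, drop = FALSE], m0$outcome)
    list(importance = tab, additive = add, odds = ors)
  })
  utils::write.table(imp$importance, file.path(out_dir, "importance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(imp$additive, file.path(out_dir, "additive_auroc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(imp$odds, file.path(out_dir, "odds_ratios.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- enrich ----------------------------------------------------------
  enr <- run_stage("enrich", function() {
    if (is.null(sets)) return(NULL)
    bg <- background_rank_model(nrow(fit$A), set_size = config$set_size,
                                iterations = config$iterations,
                                n_patterns = config$K,
                                seed = config$seed + 4L)
    set.seed(config$seed + 4L)
    bg_ranks <- sample.int(nrow(fit$A), 500L, replace = TRUE)
    rows <- list()
    for (k in seq_len(fit$K)) {
      ranked <- rank_genes_by_amplitude(fit, k)
      for (nm in names(sets)) {
        cr <- tryCatch(cumulative_rank_statistic(ranked, sets[[nm]], nm),
                       error = function(e) NULL)
        if (is.null(cr)) next
        ks <- ks_exact_two_sample(cr$ranks, bg_ranks)
        rows[[length(rows) + 1L]] <- data.frame(
          set = nm, pattern = rownames(fit$P)[k], sum_rank = cr$sum_rank,
          n_present = cr$n_present, mean_rank = cr$sum_rank / cr$n_present,
          bg_mean_rank = bg$mean_rank, ks_D = ks$D, ks_p = ks$p,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(enr))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

  # --- trajectory ------------------------------------------------------
  traj <- run_stage("trajectory", function() {
    cls_tab <- cls$classes
    ax1 <- cls_tab$pattern[cls_tab$class == "prognostic"][1]
    ax2 <- cls_tab$pattern[cls_tab$class == "dynamic"][1]
    if (is.na(ax1)) ax1 <- rownames(fit$P)[1]
    if (is.na(ax2)) ax2 <- setdiff(rownames(fit$P), ax1)[1]
    ts <- group_mean_trajectory(fit$P, meta, c(ax1, ax2))
    pca <- run_pca(lg, n_components = 2L)
    rec <- recovery_index(stats::setNames(pca$scores[, 1],
                                          rownames(pca$scores)), meta)
    list(summary = ts, recovery = rec)
  })
  utils::write.table(traj$summary$table, file.path(out_dir, "trajectory.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(traj$recovery$per_subject,
                     file.path(out_dir, "recovery.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  write_manifest(list(
    package = as.character(utils::packageVersion("sepsisPatterns")),
    seed = config$seed, simulated = sim, K = config$K,
    n_genes_input = nrow(expr$values), n_genes_factorized = nrow(fit$A),
    n_samples = ncol(expr$values), tol = config$tol,
    max_iter = config$max_iter, n_restarts = config$n_restarts,
    auroc_threshold = config$auroc_threshold,
    resplits = config$resplits, folds = config$folds,
    repeats = config$repeats, n_perm = config$n_perm,
    iterations = config$iterations, set_size = config$set_size
  ), file.path(out_dir, "manifest.txt"))
  writeLines(log_lines, log_path)
  invisible(out_dir)
}
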