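#' Configuration for an end-to-end discovery run
#'
#' Collects every tunable of the pipeline in one place; the defaults are
#' the discovery protocol's stated constants (2.5 x IQR above Q75,
#' candidate score difference > 5, top-20 rank lists over 1000 forests,
#' a panel of at most 10 markers). Unknown options are rejected because
#' the constructor takes only named arguments.
#'
#' @param input optional path to a spot-level table; when NULL a
#'   synthetic cohort is generated from `sim`.
#' @param sim a [sim_config()] used when `input` is NULL; its seed is
#'   overridden by the pipeline master `seed`.
#' @param outdir optional output directory for stage outputs and the run
#'   manifest.
#' @param basis cutoff basis, `"all"` or `"controls"`.
#' @param iqr_multiplier IQR multiplier for the seroreactivity cutoff.
#' @param candidate_threshold strict biomarker score-difference threshold.
#' @param top_k rank-list length per forest run.
#' @param n_runs number of random-forest runs.
#' @param n_trees trees per forest.
#' @param mtry features per split (NULL = `floor(sqrt(p))`).
#' @param forest_mode `"regression"` or `"classification"`.
#' @param max_panel_size panel cap for the classification tree.
#' @param cv_folds cross-validation folds for tree pruning.
#' @param min_rho,max_cv array QC thresholds.
#' @param skip_quantile skip inter-array quantile normalisation.
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + 1 ... seed + n_runs` (forest runs, inside
#'   [run_forest_ensemble()] from `seed + 1009`) and `seed + 2003`
#'   (tree cross-validation).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(), outdir = NULL,
                            basis = c("all", "controls"),
                            iqr_multiplier = 2.5, candidate_threshold = 5,
                            top_k = 20L, n_runs = 1000L, n_trees = 500L,
                            mtry = NULL,
                            forest_mode = c("regression", "classification"),
                            max_panel_size = 10L, cv_folds = 10L,
                            min_rho = 0.5, max_cv = 0.5,
                            skip_quantile = FALSE, seed = 1L) {
  basis <- basis[1L]
  .chk_field(basis %in% c("all", "controls"), "basis",
             "must be 'all' or 'controls'")
  forest_mode <- forest_mode[1L]
  .chk_field(forest_mode %in% c("regression", "classification"),
             "forest_mode", "must be 'regression' or 'classification'")
  .chk_field(iqr_multiplier > 0, "iqr_multiplier", "must be positive")
  .chk_field(top_k >= 1, "top_k", "must be a positive count")
  .chk_field(n_runs >= 1, "n_runs", "must be a positive count")
  .chk_field(n_trees >= 1, "n_trees", "must be a positive count")
  .chk_field(max_panel_size >= 1, "max_panel_size",
             "must be a positive count")
  .chk_field(cv_folds >= 2, "cv_folds", "must be at least 2")
  structure(list(
    input = input, sim = sim, outdir = outdir, basis = basis,
    iqr_multiplier = iqr_multiplier,
    candidate_threshold = candidate_threshold,
    top_k = as.integer(top_k), n_runs = as.integer(n_runs),
    n_trees = as.integer(n_trees), mtry = mtry, forest_mode = forest_mode,
    max_panel_size = as.integer(max_panel_size),
    cv_folds = as.integer(cv_folds), min_rho = min_rho, max_cv = max_cv,
    skip_quantile = skip_quantile, seed = as.integer(seed)
  ), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

.md5_of_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Run the whole discovery pipeline
#'
#' Executes, in order: data simulation or ingestion, background
#' subtraction, replicate collapse, reference-serum QC with exclusion,
#' intra-array and quantile normalisation, cutoff computation and
#' dichotomisation, biomarker scoring and candidate selection, the
#' two-stage panel selector, and evaluation (serum scores, breadth,
#' rank-sum test, ROC). Rerunning with an identical config reproduces
#' identical outputs; when `outdir` is set, all stage outputs are written
#' as TSV/text plus a JSON run manifest whose file hashes are chained for
#' integrity checking.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log messages.
#' @return A `sero_pipeline` result list (matrix, qc, cutoffs, calls,
#'   scores, candidates, aggregation, panel, serum, breadth, tests,
#'   truth, manifest).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[seroscreen] ", fmt), ...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## -- data -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    dataset <- run_stage("ingest", read_spot_table(config$input))
    reference <- NULL
    log_stage("ingest: %d arrays, %d spot records",
              nrow(dataset$samples), nrow(dataset$spots))
  } else {
    sim <- config$sim
    sim$seed <- config$seed
    gen <- run_stage("simulate", generate_cohort(sim))
    dataset <- gen$dataset
    truth <- gen$truth
    reference <- generate_reference_serum(sim)
    log_stage("simulate: %d arrays x %d antigens (%d planted)",
              nrow(dataset$samples), sim$n_antigens, sim$n_planted)
  }

  ## -- QC + normalisation ---------------------------------------------
  n_arrays_in <- nrow(dataset$samples)
  x <- run_stage("normalize", normalize_arrays(
    dataset, reference = reference, min_rho = config$min_rho,
    max_cv = config$max_cv, skip_quantile = config$skip_quantile
  ))
  n_excluded <- if (!is.null(x$qc)) sum(!x$qc$pass) else 0L
  log_stage("normalize: %d arrays retained (%d QC-excluded), steps: %s",
            nrow(x$intensity), n_excluded,
            paste(x$normalization, collapse = " -> "))

  ## -- seroreactivity --------------------------------------------------
  cutoffs <- run_stage("discover", compute_cutoffs(
    x, basis = config$basis, multiplier = config$iqr_multiplier
  ))
  calls <- run_stage("discover", dichotomize(x, cutoffs))
  scores <- run_stage("discover", biomarker_scores(calls))
  candidates <- run_stage("discover", select_candidates(
    scores, threshold = config$candidate_threshold
  ))
  log_stage("discover: basis=%s, %d candidate antigen(s) with score diff > %g",
            config$basis, length(candidates), config$candidate_threshold)

  ## -- panel -----------------------------------------------------------
  aggregation <- NULL
  panel <- NULL
  if (length(candidates) >= 2L) {
    feats <- x$intensity[, candidates, drop = FALSE]
    runs <- run_stage("panel", run_forest_ensemble(
      feats, x$cohort, n_runs = config$n_runs, n_trees = config$n_trees,
      mtry = config$mtry, seed = config$seed + 1009L, top_k = config$top_k,
      mode = config$forest_mode
    ))
    aggregation <- aggregate_runs(runs)
    stage2 <- select_stage2_features(aggregation)
    panel <- run_stage("panel", fit_panel_tree(
      x$intensity[, stage2, drop = FALSE], x$cohort,
      max_panel_size = config$max_panel_size, cv_folds = config$cv_folds,
      seed = config$seed + 2003L, calls = calls
    ))
    log_stage("panel: union of %d antigen(s); tree panel of %d marker(s)",
              nrow(aggregation), length(panel$panel))
  } else {
    log_stage("panel: skipped (fewer than 2 candidates)")
  }

  ## -- evaluation -------------------------------------------------------
  serum_all <- run_stage("evaluate", serum_scores(x, cutoffs))
  serum_cand <- if (length(candidates) > 0L) {
    serum_scores(x, cutoffs, subset = candidates)
  }
  ranksum <- if (length(candidates) > 0L) {
    compare_groups(serum_cand$samples$serum_score,
                   serum_cand$samples$cohort, test = "ranksum")
  }
  breadth <- breadth_summary(calls)
  log_stage("evaluate: serum-score rank-sum p = %s",
            if (!is.null(ranksum)) format.pval(ranksum$p_value) else "NA")

  result <- structure(list(
    matrix = x, qc = x$qc, cutoffs = cutoffs, calls = calls,
    scores = scores, candidates = candidates, aggregation = aggregation,
    panel = panel, serum = serum_all, serum_candidates = serum_cand,
    breadth = breadth, tests = list(ranksum = ranksum), truth = truth,
    config = config
  ), class = "sero_pipeline")

  ## -- outputs + manifest ----------------------------------------------
  if (!is.null(config$outdir)) {
    result$manifest <- .write_pipeline_outputs(result, config)
  }
  result
}

.write_pipeline_outputs <- function(result, config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  x <- result$matrix
  files <- character()

  mat_df <- cbind(
    data.frame(sample_id = rownames(x$intensity),
               cohort = as.character(x$cohort), stringsAsFactors = FALSE),
    as.data.frame(x$intensity)
  )
  files["normalized_matrix"] <- .write_tsv(mat_df,
    file.path(outdir, "normalized_matrix.tsv"))
  files["cutoffs"] <- .write_tsv(as.data.frame(result$cutoffs),
    file.path(outdir, "cutoffs.tsv"))
  files["biomarker_scores"] <- .write_tsv(as.data.frame(result$scores),
    file.path(outdir, "biomarker_scores.tsv"))
  writeLines(result$candidates, file.path(outdir, "candidates.txt"))
  files["candidates"] <- file.path(outdir, "candidates.txt")
  if (!is.null(result$qc)) {
    files["qc_report"] <- .write_tsv(as.data.frame(result$qc),
      file.path(outdir, "qc_report.tsv"))
  }
  if (!is.null(result$aggregation)) {
    files["rank_aggregation"] <- .write_tsv(
      as.data.frame(result$aggregation),
      file.path(outdir, "rank_aggregation.tsv"))
  }
  if (!is.null(result$panel)) {
    writeLines(result$panel$panel, file.path(outdir, "panel.txt"))
    files["panel"] <- file.path(outdir, "panel.txt")
    files["panel_metrics"] <- .write_tsv(result$panel$metrics,
      file.path(outdir, "panel_metrics.tsv"))
    if (!is.null(result$panel$cumulative)) {
      files["cumulative_metrics"] <- .write_tsv(result$panel$cumulative,
        file.path(outdir, "cumulative_metrics.tsv"))
    }
  }
  files["serum_scores"] <- .write_tsv(result$serum$samples,
    file.path(outdir, "serum_scores.tsv"))

  md5 <- vapply(files, function(f) unname(tools::md5sum(f)), character(1))
  chain <- character(length(md5))
  prev <- ""
  for (i in seq_along(md5)) {
    prev <- .md5_of_string(paste0(prev, md5[i]))
    chain[i] <- prev
  }
  names(chain) <- names(md5)

  cfg_snapshot <- unclass(config)
  cfg_snapshot$sim <- unclass(cfg_snapshot$sim)
  manifest <- list(
    package = "seroscreen",
    version = as.character(utils::packageVersion("seroscreen")),
    config = cfg_snapshot,
    seeds = list(master = config$seed,
                 forest = config$seed + 1009L,
                 tree = config$seed + 2003L),
    counts = list(
      arrays_retained = nrow(x$intensity),
      arrays_qc_excluded = if (!is.null(result$qc)) {
        sum(!result$qc$pass)
      } else 0L,
      antigens = ncol(x$intensity),
      candidates = length(result$candidates),
      union_list = if (!is.null(result$aggregation)) {
        nrow(result$aggregation)
      } else 0L,
      panel_size = if (!is.null(result$panel)) {
        length(result$panel$panel)
      } else 0L
    ),
    files = as.list(md5),
    hash_chain = as.list(chain),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest
}

#' One-page human-readable summary of a pipeline run
#'
#' @param result a `sero_pipeline` from [run_pipeline()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "sero_pipeline"))
  cfg <- result$config
  lines <- c(
    "seroscreen discovery run",
    "========================",
    sprintf("samples: %d (%s)", nrow(result$matrix$intensity),
            paste(sprintf("%s=%d", names(table(result$matrix$cohort)),
                          table(result$matrix$cohort)), collapse = ", ")),
    sprintf("antigens: %d", ncol(result$matrix$intensity)),
    sprintf("normalisation: %s",
            paste(result$matrix$normalization, collapse = " -> ")),
    sprintf("QC-excluded arrays: %d",
            if (!is.null(result$qc)) sum(!result$qc$pass) else 0L),
    sprintf("cutoff basis: %s (Q75 + %g x IQR, type-7 quantiles)",
            attr(result$cutoffs, "basis"), attr(result$cutoffs, "multiplier")),
    sprintf("candidates (score diff > %g): %d", cfg$candidate_threshold,
            length(result$candidates))
  )
  if (!is.null(result$aggregation)) {
    lines <- c(lines, sprintf(
      "rank aggregation: union of %d antigens over %d forest runs",
      nrow(result$aggregation), attr(result$aggregation, "n_runs")
    ))
  }
  if (!is.null(result$panel)) {
    m <- result$panel$metrics
    lines <- c(lines,
      sprintf("panel (first-use order): %s",
              paste(result$panel$panel, collapse = ", ")),
      vapply(seq_len(nrow(m)), function(i) {
        sprintf("  %s rule: sensitivity %.1f%%, specificity %.1f%%, AUC %.3f",
                m$rule[i], 100 * m$sensitivity[i], 100 * m$specificity[i],
                m$auc[i])
      }, character(1))
    )
  }
  if (!is.null(result$tests$ranksum)) {
    lines <- c(lines, sprintf(
      "serum-score rank-sum (candidates): p = %s (%s)",
      format.pval(result$tests$ranksum$p_value),
      result$tests$ranksum$variant
    ))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
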