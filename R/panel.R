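#' Fit one random forest and rank its most important antigens
#'
#' Fits a random forest to the patient/control outcome on the candidate
#' antigen intensities and extracts per-antigen importance. By default a
#' regression forest is fitted on the numeric 0/1 outcome with permutation
#' importance; `mode = "classification"` fits a classification forest with
#' Gini (impurity) importance instead. The `top_k` most important antigens
#' receive rank scores `top_k` (most important) down to 1; when fewer than
#' `top_k` features exist, the top-k anchor is kept (scores `top_k` down
#' to `top_k - p + 1`). Importance ties are broken by the stable antigen
#' column order.
#'
#' @param features samples x antigens matrix (or `intensity_matrix`)
#'   restricted to the candidate antigens.
#' @param labels cohort labels (`"patient"`/`"control"`).
#' @param n_trees number of trees.
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed; single-threaded so runs are deterministic.
#' @param top_k length of the ranked list (default 20).
#' @param mode `"regression"` (default) or `"classification"`.
#' @return A `forest_run` object: `$seed`, `$mode`, `$importance` (named
#'   vector), `$top` (data frame antigen_id, importance, rank_score).
#' @export
run_forest <- function(features, labels, n_trees = 500, mtry = NULL,
                       seed = 1L, top_k = 20L,
                       mode = c("regression", "classification")) {
  mode <- match.arg(mode)
  m <- .intensity_of(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: both cohorts must be present", call. = FALSE)
  }
  if (ncol(m) < 2L) {
    stop("at least 2 candidate antigens required", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("at least 2 samples per class required", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(m))))
  x <- as.data.frame(m)
  colnames(x) <- colnames(m)
  y <- if (mode == "regression") {
    as.numeric(labels == "patient")
  } else {
    factor(labels, levels = c("control", "patient"))
  }
  fit <- ranger::ranger(
    x = x, y = y, num.trees = n_trees, mtry = mtry,
    importance = if (mode == "regression") "permutation" else "impurity",
    seed = seed, num.threads = 1L
  )
  imp <- fit$variable.importance[colnames(m)]
  ord <- order(-imp)  # stable: ties keep antigen column order
  k <- min(top_k, ncol(m))
  top <- data.frame(
    antigen_id = colnames(m)[ord[seq_len(k)]],
    importance = unname(imp[ord[seq_len(k)]]),
    rank_score = seq(top_k, top_k - k + 1L),
    stringsAsFactors = FALSE
  )
  structure(list(seed = seed, mode = mode, importance = imp, top = top),
            class = "forest_run")
}

#' Repeat the random-forest ranking many times
#'
#' Runs [run_forest()] `n_runs` times with run seeds derived from the
#' master seed by a counter scheme (`seed + 1, seed + 2, ...`), so the
#' whole ensemble is reproducible and each run independently re-runnable.
#'
#' @inheritParams run_forest
#' @param n_runs number of forests (the discovery protocol uses 1000).
#' @return A list of `forest_run` objects (class `forest_ensemble`).
#' @export
run_forest_ensemble <- function(features, labels, n_runs = 1000L,
                                n_trees = 500, mtry = NULL, seed = 1L,
                                top_k = 20L,
                                mode = c("regression", "classification")) {
  mode <- match.arg(mode)
  stopifnot(n_runs >= 1L)
  runs <- lapply(seq_len(n_runs), function(i) {
    run_forest(features, labels, n_trees = n_trees, mtry = mtry,
               seed = seed + i, top_k = top_k, mode = mode)
  })
  class(runs) <- "forest_ensemble"
  runs
}

#' Aggregate repeated forest rankings into weighted mean ranks
#'
#' For every antigen appearing in at least one top-k list: the inclusion
#' proportion (fraction of runs whose top-k contains it), the average rank
#' score over those runs, and the weighted mean rank
#' `WMR = inclusion_proportion x average_rank_score`, which summarises the
#' antigen's overall importance. Sorted by descending WMR, ties broken by
#' antigen id; invariant to the order of the runs.
#'
#' @param runs a `forest_ensemble` or list of `forest_run` objects.
#' @return A `rank_aggregation` data frame: antigen_id, n_included,
#'   inclusion_proportion, average_rank_score, weighted_mean_rank.
#' @export
aggregate_runs <- function(runs) {
  stopifnot(length(runs) >= 1L)
  n_runs <- length(runs)
  all_top <- do.call(rbind, lapply(runs, `[[`, "top"))
  n_inc <- tapply(all_top$rank_score, all_top$antigen_id, length)
  avg <- tapply(all_top$rank_score, all_top$antigen_id, mean)
  tab <- data.frame(
    antigen_id = names(n_inc),
    n_included = as.integer(n_inc),
    inclusion_proportion = as.numeric(n_inc) / n_runs,
    average_rank_score = as.numeric(avg),
    stringsAsFactors = FALSE
  )
  tab$weighted_mean_rank <- tab$inclusion_proportion * tab$average_rank_score
  tab <- tab[order(-tab$weighted_mean_rank, tab$antigen_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_runs") <- n_runs
  class(tab) <- c("rank_aggregation", "data.frame")
  tab
}

#' Choose the feature list for the classification-tree stage
#'
#' Default rule: the full union of all top-k lists (the discovery
#' protocol's behaviour). The alternative `"top_m"` rule keeps the `m`
#' antigens with the highest weighted mean rank.
#'
#' @param aggregation a `rank_aggregation` data frame.
#' @param rule `"union"` (default) or `"top_m"`.
#' @param m list length for `rule = "top_m"`.
#' @return Character vector of antigen ids (ordered by descending WMR),
#'   with the chosen rule recorded as an attribute.
#' @export
select_stage2_features <- function(aggregation, rule = c("union", "top_m"),
                                   m = NULL) {
  rule <- match.arg(rule)
  stopifnot(nrow(aggregation) >= 1L)
  ids <- aggregation$antigen_id
  if (rule == "top_m") {
    if (is.null(m)) stop("'m' required for rule = 'top_m'", call. = FALSE)
    ids <- head(ids, m)
  }
  attr(ids, "rule") <- rule
  ids
}

.tree_panel <- function(tree) {
  v <- as.character(tree$frame$var)
  unique(v[v != "<leaf>"])
}

.sens_spec <- function(predicted_patient, labels) {
  pat <- labels == "patient"
  c(sensitivity = mean(predicted_patient[pat]),
    specificity = mean(!predicted_patient[!pat]))
}

#' Fit the classification-tree stage and extract the biomarker panel
#'
#' Grows a binary CART (Gini impurity) on the stage-2 antigen
#' intensities and prunes it by cost-complexity until the panel — the
#' distinct split antigens in first-use (pre-)order — fits
#' `max_panel_size`. The default `prune_rule = "cap"` prunes only to the
#' cap, mirroring discovery protocols that report the apparent
#' (resubstitution) performance of a full-size marker panel; the
#' conservative alternatives `"1se"` (cross-validated 1-SE rule, falling
#' back to the minimum-error tree when 1-SE selects the root stump) and
#' `"min"` (minimum cross-validated error) prune by CV first and then
#' apply the cap. Performance is reported under both decision rules: the
#' tree rule (leaf class with leaf-probability ROC) and, when
#' seroreactivity calls are supplied, the any-positive rule with its
#' positive-count ROC.
#'
#' @param features samples x antigens matrix (or `intensity_matrix`)
#'   restricted to the stage-2 antigens.
#' @param labels cohort labels (`"patient"`/`"control"`).
#' @param max_panel_size maximum number of distinct split antigens.
#' @param cv_folds cross-validation folds for pruning.
#' @param seed seed for the cross-validation fold assignment.
#' @param minsplit,cp [rpart::rpart.control()] growth parameters.
#' @param prune_rule `"cap"` (default), `"1se"` or `"min"`; see Details.
#' @param calls optional `sero_calls` for any-positive metrics.
#' @return A `panel_model`: `$tree` (pruned rpart), `$panel` (ordered
#'   antigen ids), `$cp`, `$predictions` (per-sample leaf probability and
#'   tree class), `$metrics` (tree-rule and any-positive sensitivity /
#'   specificity / AUC), `$cumulative` (per-added-marker metrics, when
#'   `calls` given).
#' @export
fit_panel_tree <- function(features, labels, max_panel_size = 10L,
                           cv_folds = 10L, seed = 1L, minsplit = 10L,
                           cp = 0.002, prune_rule = c("cap", "1se", "min"),
                           calls = NULL) {
  prune_rule <- match.arg(prune_rule)
  m <- .intensity_of(features)
  labels <- as.character(labels)
  if (ncol(m) < 1L) stop("empty stage-2 antigen list", call. = FALSE)
  if (all(apply(m, 2L, function(col) length(unique(col)) <= 1L))) {
    stop("all features are constant: no split possible", call. = FALSE)
  }
  ## rpart formulas need syntactic names; keep a map back to antigen ids
  safe <- make.names(colnames(m), unique = TRUE)
  name_map <- stats::setNames(colnames(m), safe)
  df <- as.data.frame(m)
  colnames(df) <- safe
  df$.outcome <- factor(labels, levels = c("control", "patient"))
  set.seed(seed)
  fit <- rpart::rpart(
    .outcome ~ ., data = df, method = "class",
    control = rpart::rpart.control(minsplit = minsplit, cp = cp,
                                   xval = cv_folds)
  )
  cpt <- fit$cptable
  if (is.null(cpt) || nrow(cpt) == 0L || max(cpt[, "nsplit"]) == 0L) {
    pruned <- fit
    cp_used <- cp
  } else {
    i_sel <- nrow(cpt)  # "cap": keep the grown tree, prune only to the cap
    if (prune_rule != "cap") {
      i_min <- which.min(cpt[, "xerror"])
      if (prune_rule == "min") {
        i_sel <- i_min
      } else {
        thr <- cpt[i_min, "xerror"] + cpt[i_min, "xstd"]
        i_sel <- min(which(cpt[, "xerror"] <= thr))
        if (cpt[i_sel, "nsplit"] == 0L && cpt[i_min, "nsplit"] > 0L) {
          i_sel <- i_min  # 1-SE picked the stump; keep best CV tree instead
        }
      }
    }
    pruned <- rpart::prune(fit, cp = cpt[i_sel, "CP"])
    ## raise the complexity penalty until the panel fits the cap
    j <- i_sel
    while (length(.tree_panel(pruned)) > max_panel_size && j > 1L) {
      j <- j - 1L
      pruned <- rpart::prune(fit, cp = cpt[j, "CP"])
    }
    cp_used <- cpt[j, "CP"]
  }
  panel <- unname(name_map[.tree_panel(pruned)])
  prob <- predict(pruned, type = "prob")[, "patient"]
  cls <- predict(pruned, type = "class")
  tree_ss <- .sens_spec(cls == "patient", labels)
  tree_auc <- roc_auc(prob, labels)$auc
  metrics <- data.frame(
    rule = "tree",
    sensitivity = tree_ss[["sensitivity"]],
    specificity = tree_ss[["specificity"]],
    auc = tree_auc,
    stringsAsFactors = FALSE
  )
  cumulative <- NULL
  if (!is.null(calls) && length(panel) > 0L) {
    ap <- any_positive_classify(calls, panel)
    ap_labels <- as.character(calls$cohort)
    ap_ss <- .sens_spec(ap$predicted == "patient", ap_labels)
    ap_auc <- roc_auc(ap$n_positive, ap_labels)$auc
    metrics <- rbind(metrics, data.frame(
      rule = "any_positive",
      sensitivity = ap_ss[["sensitivity"]],
      specificity = ap_ss[["specificity"]],
      auc = ap_auc,
      stringsAsFactors = FALSE
    ))
    cumulative <- cumulative_panel_metrics(calls, ap_labels, panel)
  }
  structure(list(
    tree = pruned, full_tree = fit, panel = panel, cp = cp_used,
    predictions = data.frame(array_id = rownames(m),
                             prob_patient = unname(prob),
                             tree_class = as.character(cls),
                             stringsAsFactors = FALSE),
    metrics = metrics, cumulative = cumulative
  ), class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %d markers (%s)\n", length(x$panel),
              paste(x$panel, collapse = ", ")))
  print(x$metrics)
  invisible(x)
}

#' Classify samples by the any-positive panel rule
#'
#' A sample is predicted to be a patient when it is seroreactive for at
#' least one panel antigen. The integer count of positive panel antigens
#' is returned as a ROC-able score.
#'
#' @param calls a `sero_calls` object.
#' @param panel non-empty character vector of panel antigen ids.
#' @return Data frame: array_id, n_positive, predicted.
#' @export
any_positive_classify <- function(calls, panel) {
  stopifnot(inherits(calls, "sero_calls"))
  if (length(panel) == 0L) {
    stop("empty panel", call. = FALSE)
  }
  missing_ag <- setdiff(panel, colnames(calls$positive))
  if (length(missing_ag) > 0L) {
    stop(sprintf("panel antigen(s) not in calls: %s",
                 paste(missing_ag, collapse = ", ")), call. = FALSE)
  }
  cnt <- rowSums(calls$positive[, panel, drop = FALSE])
  data.frame(
    array_id = rownames(calls$positive),
    n_positive = unname(cnt),
    predicted = ifelse(cnt >= 1L, "patient", "control"),
    stringsAsFactors = FALSE
  )
}

#' Cumulative any-positive sensitivity and specificity of an ordered panel
#'
#' For `k = 1 ... |panel|`, computes the any-positive sensitivity and
#' specificity using only the first `k` markers. Sensitivity is
#' non-decreasing and specificity non-increasing in `k`.
#'
#' @param calls a `sero_calls` object.
#' @param labels cohort labels; defaults to labels stored in `calls`.
#' @param panel ordered character vector of panel antigen ids.
#' @return Data frame: k, antigen_id, sensitivity, specificity.
#' @export
cumulative_panel_metrics <- function(calls, labels = NULL, panel) {
  stopifnot(inherits(calls, "sero_calls"), length(panel) >= 1L)
  if (is.null(labels)) labels <- calls$cohort
  labels <- as.character(labels)
  rows <- lapply(seq_along(panel), function(k) {
    cnt <- rowSums(calls$positive[, panel[seq_len(k)], drop = FALSE])
    ss <- .sens_spec(cnt >= 1L, labels)
    data.frame(k = k, antigen_id = panel[k],
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
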