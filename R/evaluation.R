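#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (predicted
#' "patient" when score > threshold) and computes the ROC curve and its
#' trapezoidal area. The AUC equals the Mann-Whitney concordance
#' probability: the proportion of patient-control pairs where the patient
#' scores higher, ties counted one half.
#'
#' @param scores numeric score per sample (higher = more patient-like).
#' @param labels cohort labels (`"patient"`/`"control"`) or a logical
#'   vector (TRUE = patient).
#' @param threshold optional operating threshold at which sensitivity and
#'   specificity are reported (positive when score > threshold).
#' @return A `roc_result`: `$points` (threshold, fpr, tpr; sorted by fpr,
#'   starting at (0,0) and ending at (1,1)), `$auc`, `$operating` (when a
#'   threshold was given).
#' @export
roc_auc <- function(scores, labels, threshold = NULL) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    pos <- as.character(labels) == "patient"
  }
  if (!any(pos) || all(pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- pos[o]
  ends <- cumsum(rle(s)$lengths)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  tpr <- c(0, cumsum(y)[ends] / n_pos)
  fpr <- c(0, cumsum(!y)[ends] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  points <- data.frame(threshold = c(Inf, s[ends]), fpr = fpr, tpr = tpr)
  operating <- NULL
  if (!is.null(threshold)) {
    operating <- data.frame(
      threshold = threshold,
      sensitivity = mean(scores[pos] > threshold),
      specificity = mean(scores[!pos] <= threshold)
    )
  }
  structure(list(points = points, auc = auc, operating = operating),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d thresholds)\n", x$auc,
              nrow(x$points) - 1L))
  if (!is.null(x$operating)) print(x$operating)
  invisible(x)
}

#' Nonparametric group comparisons and normality screening
#'
#' Wraps the rank-based tests used throughout the analysis. For the
#' two-group rank-sum (Mann-Whitney U) test, the exact null distribution
#' is enumerated when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and
#' continuity correction is used, and the variant is recorded in the
#' result. All p-values are two-sided.
#'
#' @param values numeric response per sample (for `"spearman"`, the first
#'   paired vector).
#' @param grouping group labels (for `"spearman"`, the second paired
#'   numeric vector).
#' @param test `"ranksum"`, `"kruskal"`, `"spearman"` or `"shapiro"`
#'   (per-group normality screening, reported but never gating).
#' @return A `group_test` object: test, statistic, p_value, variant and a
#'   per-group summary (n, median, q25, q75) where applicable.
#' @export
compare_groups <- function(values, grouping,
                           test = c("ranksum", "kruskal", "spearman",
                                    "shapiro")) {
  test <- match.arg(test)
  if (test == "spearman") {
    if (length(values) != length(grouping)) {
      stop("paired vectors must have equal length", call. = FALSE)
    }
    ht <- suppressWarnings(cor.test(values, grouping, method = "spearman"))
    res <- list(test = "spearman", statistic = unname(ht$estimate),
                p_value = ht$p.value,
                variant = "rho; asymptotic t approximation when tied",
                group_summary = NULL)
    class(res) <- "group_test"
    return(res)
  }
  g <- factor(grouping)
  sizes <- table(g)
  if (any(sizes == 0L)) {
    stop("every group must contain at least one observation", call. = FALSE)
  }
  gs <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = lv, n = length(v), median = q[2L], q25 = q[1L],
               q75 = q[3L], stringsAsFactors = FALSE)
  }))
  if (test == "ranksum") {
    if (nlevels(g) != 2L) {
      stop("rank-sum test requires exactly 2 groups", call. = FALSE)
    }
    x <- values[g == levels(g)[1L]]
    y <- values[g == levels(g)[2L]]
    exact <- (length(x) + length(y)) <= 20L && !anyDuplicated(values)
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    res <- list(test = "ranksum", statistic = unname(ht$statistic),
                p_value = ht$p.value,
                variant = if (exact) "exact enumeration" else
                  "normal approximation, tie and continuity corrected",
                group_summary = gs)
  } else if (test == "kruskal") {
    if (nlevels(g) < 2L) {
      stop("Kruskal-Wallis requires at least 2 groups", call. = FALSE)
    }
    ht <- kruskal.test(values, g)
    res <- list(test = "kruskal", statistic = unname(ht$statistic),
                p_value = ht$p.value,
                variant = "chi-squared approximation, tie corrected",
                group_summary = gs)
  } else {  # shapiro
    res_by_group <- lapply(levels(g), function(lv) {
      ht <- shapiro.test(values[g == lv])
      c(statistic = unname(ht$statistic), p_value = ht$p.value)
    })
    w <- vapply(res_by_group, `[[`, numeric(1), "statistic")
    p <- vapply(res_by_group, `[[`, numeric(1), "p_value")
    names(w) <- names(p) <- levels(g)
    res <- list(test = "shapiro", statistic = w, p_value = p,
                variant = "per-group Shapiro-Wilk", group_summary = gs)
  }
  class(res) <- "group_test"
  res
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s test (%s)\n", x$test, x$variant))
  cat("statistic:", format(x$statistic), " p:", format(x$p_value), "\n")
  if (!is.null(x$group_summary)) print(x$group_summary)
  invisible(x)
}

#' Cross-site / replicate concordance by Spearman correlation
#'
#' For specimens measured twice (e.g. at two screening sites), computes
#' the Spearman correlation between the two intensity vectors of each
#' shared specimen and flags pairs exceeding the concordance threshold.
#'
#' @param a,b matrices (specimens x antigens, matching rows) or a single
#'   pair of numeric vectors; vectors must have length >= 3.
#' @param threshold minimum rho to pass (default 0.5).
#' @return A data frame (pair_id, rho, pass) with attribute
#'   `fraction_passing`.
#' @export
concordance <- function(a, b, threshold = 0.5) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (!all(dim(a) == dim(b))) {
    stop("paired intensity sets must have matching dimensions",
         call. = FALSE)
  }
  if (ncol(a) < 3L) {
    stop("paired vectors must have length >= 3", call. = FALSE)
  }
  rho <- vapply(seq_len(nrow(a)), function(i) {
    suppressWarnings(cor(a[i, ], b[i, ], method = "spearman"))
  }, numeric(1))
  ids <- rownames(a)
  if (is.null(ids)) ids <- sprintf("pair%03d", seq_len(nrow(a)))
  out <- data.frame(pair_id = ids, rho = rho, pass = rho > threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "fraction_passing") <- mean(out$pass)
  out
}
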