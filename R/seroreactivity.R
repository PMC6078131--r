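.intensity_of <- function(x) {
  if (inherits(x, "intensity_matrix")) x$intensity else as.matrix(x)
}

.cohort_of <- function(x, labels) {
  if (!is.null(labels)) {
    return(as.character(labels))
  }
  if (inherits(x, "intensity_matrix")) {
    return(as.character(x$cohort))
  }
  NULL
}

#' Per-antigen seroreactivity cutoffs: Q75 + 2.5 x IQR
#'
#' For each antigen, the cutoff is the 75th percentile plus `multiplier`
#' times the interquartile range of the normalised intensities over the
#' basis samples. Quartiles use linear interpolation between order
#' statistics (R's default type-7 convention); the convention and basis
#' are recorded as attributes because the cutoffs depend on them.
#'
#' @param x an `intensity_matrix` (or plain samples x antigens matrix).
#' @param basis `"all"` (default): all discovery samples; `"controls"`:
#'   control samples only.
#' @param multiplier IQR multiplier above Q75 (default 2.5).
#' @param labels optional cohort labels when `x` is a plain matrix.
#' @return A `cutoff_table` data frame: antigen_id, q25, q75, iqr, cutoff,
#'   with attributes `basis`, `multiplier`, `quantile_type`.
#' @export
compute_cutoffs <- function(x, basis = c("all", "controls"),
                            multiplier = 2.5, labels = NULL) {
  basis <- match.arg(basis)
  m <- .intensity_of(x)
  if (basis == "controls") {
    cohort <- .cohort_of(x, labels)
    if (is.null(cohort)) {
      stop("cohort labels required for basis = 'controls'", call. = FALSE)
    }
    m <- m[cohort == "control", , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    stop("empty basis sample set", call. = FALSE)
  }
  if (nrow(m) < 4L) {
    stop("fewer than 4 samples in the cutoff basis", call. = FALSE)
  }
  q <- apply(m, 2L, quantile, probs = c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L, ] - q[1L, ]
  tab <- data.frame(
    antigen_id = colnames(m),
    q25 = unname(q[1L, ]),
    q75 = unname(q[2L, ]),
    iqr = unname(iqr),
    cutoff = unname(q[2L, ] + multiplier * iqr),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "basis") <- basis
  attr(tab, "multiplier") <- multiplier
  attr(tab, "quantile_type") <- 7L
  class(tab) <- c("cutoff_table", "data.frame")
  tab
}

#' Dichotomise intensities into seroreactivity calls and S/C ratios
#'
#' A sample is positive for an antigen when its intensity is strictly
#' above the antigen's cutoff; for positive calls the signal-to-cutoff
#' (S/C) ratio `intensity / cutoff` is recorded (always > 1), otherwise
#' the ratio is absent (NA). Antigens with cutoff <= 0 (possible when an
#' antigen is zero after background flooring) are unscorable and are
#' excluded from the calls with a warning.
#'
#' @param x an `intensity_matrix` or samples x antigens matrix.
#' @param cutoffs a `cutoff_table` covering all antigens of `x`.
#' @param labels optional cohort labels when `x` is a plain matrix.
#' @return A `sero_calls` object: `$positive` (logical matrix),
#'   `$sc_ratio` (numeric matrix, NA where negative), `$cutoffs`,
#'   `$cohort`.
#' @export
dichotomize <- function(x, cutoffs, labels = NULL) {
  m <- .intensity_of(x)
  cohort <- .cohort_of(x, labels)
  missing_ag <- setdiff(colnames(m), cutoffs$antigen_id)
  if (length(missing_ag) > 0L) {
    stop(sprintf("antigen(s) missing from cutoff table: %s",
                 paste(head(missing_ag, 10L), collapse = ", ")),
         call. = FALSE)
  }
  cut <- cutoffs$cutoff[match(colnames(m), cutoffs$antigen_id)]
  scorable <- cut > 0
  if (!all(scorable)) {
    warning(sprintf("%d antigen(s) with cutoff <= 0 declared unscorable",
                    sum(!scorable)), call. = FALSE)
    m <- m[, scorable, drop = FALSE]
    cut <- cut[scorable]
  }
  positive <- sweep(m, 2L, cut, ">")
  sc <- sweep(m, 2L, cut, "/")
  sc[!positive] <- NA_real_
  keep <- cutoffs$antigen_id %in% colnames(m)
  structure(list(positive = positive, sc_ratio = sc,
                 cutoffs = cutoffs[keep, , drop = FALSE],
                 cohort = if (!is.null(cohort)) {
                   stats::setNames(cohort, rownames(m))
                 }),
            class = "sero_calls")
}

#' @export
print.sero_calls <- function(x, ...) {
  cat(sprintf("sero_calls: %d samples x %d antigens, %d positive calls\n",
              nrow(x$positive), ncol(x$positive), sum(x$positive)))
  invisible(x)
}

#' Per-antigen biomarker scores and single-marker diagnostics
#'
#' For each cohort the biomarker score of an antigen is the number of
#' positive samples multiplied by the cube root of the cohort's mean S/C
#' ratio (0 when no sample is positive). Antigens are ranked by the
#' patient minus control score difference (dense ranking, ties share a
#' rank). Single-marker sensitivity is `N_pos_patient / n_patients` and
#' specificity `1 - N_pos_control / n_controls`.
#'
#' @param calls a `sero_calls` object.
#' @param labels cohort labels (`"patient"`/`"control"`); defaults to the
#'   labels stored in `calls`.
#' @return A `biomarker_scores` data frame with one row per antigen:
#'   n_pos_patient, n_pos_control, mean_sc_patient, mean_sc_control,
#'   score_patient, score_control, score_diff, rank, sensitivity,
#'   specificity.
#' @export
biomarker_scores <- function(calls, labels = NULL) {
  stopifnot(inherits(calls, "sero_calls"))
  if (is.null(labels)) labels <- calls$cohort
  labels <- as.character(labels)
  if (length(labels) != nrow(calls$positive)) {
    stop("labels must have one entry per sample", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("patient", "control"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid cohort label(s): %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  pat <- labels == "patient"
  cohort_stats <- function(sel) {
    pos <- calls$positive[sel, , drop = FALSE]
    sc <- calls$sc_ratio[sel, , drop = FALSE]
    n_pos <- colSums(pos)
    mean_sc <- colSums(sc, na.rm = TRUE) / pmax(n_pos, 1L)
    mean_sc[n_pos == 0L] <- 0
    list(n_pos = n_pos, mean_sc = mean_sc,
         score = n_pos * mean_sc^(1 / 3))
  }
  p <- cohort_stats(pat)
  c_ <- cohort_stats(!pat)
  diff <- p$score - c_$score
  tab <- data.frame(
    antigen_id = colnames(calls$positive),
    n_pos_patient = unname(p$n_pos),
    n_pos_control = unname(c_$n_pos),
    mean_sc_patient = unname(p$mean_sc),
    mean_sc_control = unname(c_$mean_sc),
    score_patient = unname(p$score),
    score_control = unname(c_$score),
    score_diff = unname(diff),
    rank = match(diff, sort(unique(diff), decreasing = TRUE)),
    sensitivity = unname(p$n_pos) / sum(pat),
    specificity = 1 - unname(c_$n_pos) / sum(!pat),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "n_patients") <- sum(pat)
  attr(tab, "n_controls") <- sum(!pat)
  class(tab) <- c("biomarker_scores", "data.frame")
  tab
}

#' Select candidate biomarkers by the score-difference rule
#'
#' Antigens whose patient minus control biomarker score difference is
#' strictly greater than the threshold (default 5) are considered to have
#' potential diagnostic value; they are returned ordered by descending
#' score difference, ties broken by antigen id.
#'
#' @param table a `biomarker_scores` data frame.
#' @param threshold strict lower bound on the score difference.
#' @return Character vector of selected antigen ids.
#' @export
select_candidates <- function(table, threshold = 5) {
  stopifnot(is.data.frame(table), "score_diff" %in% colnames(table))
  sel <- table[table$score_diff > threshold, , drop = FALSE]
  sel <- sel[order(-sel$score_diff, sel$antigen_id), , drop = FALSE]
  sel$antigen_id
}

#' Per-sample serum scores over an antigen subset
#'
#' The serum score of a sample is the sum of its normalised intensities
#' (not the excess over the cutoff) at the subset antigens where the
#' intensity exceeds the antigen cutoff; the number of positive antibodies
#' is counted alongside. Cohort medians and quartiles are summarised.
#'
#' @param x an `intensity_matrix` or samples x antigens matrix.
#' @param cutoffs a `cutoff_table`.
#' @param subset antigen ids to restrict to (default: all antigens of the
#'   matrix that appear in the cutoff table); must be non-empty.
#' @param labels optional cohort labels when `x` is a plain matrix.
#' @return A `serum_scores` object: `$samples` data frame (array_id,
#'   cohort, serum_score, n_positive) and `$summary` per-cohort medians
#'   and quartiles.
#' @export
serum_scores <- function(x, cutoffs, subset = NULL, labels = NULL) {
  m <- .intensity_of(x)
  cohort <- .cohort_of(x, labels)
  if (is.null(subset)) {
    subset <- intersect(colnames(m), cutoffs$antigen_id)
  }
  if (length(subset) == 0L) {
    stop("empty antigen subset", call. = FALSE)
  }
  missing_ag <- setdiff(subset, colnames(m))
  if (length(missing_ag) > 0L) {
    stop(sprintf("subset antigen(s) not in matrix: %s",
                 paste(head(missing_ag, 10L), collapse = ", ")),
         call. = FALSE)
  }
  missing_cut <- setdiff(subset, cutoffs$antigen_id)
  if (length(missing_cut) > 0L) {
    stop(sprintf("subset antigen(s) missing from cutoff table: %s",
                 paste(head(missing_cut, 10L), collapse = ", ")),
         call. = FALSE)
  }
  cut <- cutoffs$cutoff[match(subset, cutoffs$antigen_id)]
  scorable <- cut > 0
  if (!all(scorable)) {
    warning(sprintf("%d unscorable antigen(s) (cutoff <= 0) dropped",
                    sum(!scorable)), call. = FALSE)
    subset <- subset[scorable]
    cut <- cut[scorable]
  }
  ms <- m[, subset, drop = FALSE]
  pos <- sweep(ms, 2L, cut, ">")
  score <- rowSums(ms * pos)
  samples <- data.frame(
    array_id = rownames(m),
    cohort = if (!is.null(cohort)) cohort else NA_character_,
    serum_score = unname(score),
    n_positive = unname(rowSums(pos)),
    stringsAsFactors = FALSE
  )
  summary <- NULL
  if (!is.null(cohort)) {
    summary <- do.call(rbind, lapply(split(samples, samples$cohort),
                                     function(d) {
      q <- quantile(d$serum_score, c(0.25, 0.5, 0.75), type = 7,
                    names = FALSE)
      data.frame(cohort = d$cohort[1L], n = nrow(d),
                 median = q[2L], q25 = q[1L], q75 = q[3L],
                 median_n_positive = stats::median(d$n_positive),
                 stringsAsFactors = FALSE)
    }))
    rownames(summary) <- NULL
  }
  structure(list(samples = samples, summary = summary, subset = subset),
            class = "serum_scores")
}

#' @export
print.serum_scores <- function(x, ...) {
  cat(sprintf("serum_scores over %d antigens\n", length(x$subset)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Breadth of the autoantibody response per cohort
#'
#' Summarises, per cohort, the number of antigens each sample is
#' seroreactive against over a stated subset (full array, candidate list
#' or panel): median and quartiles of the per-sample positive counts plus
#' the cohort's total count of positive responses.
#'
#' @param calls a `sero_calls` object.
#' @param labels cohort labels; defaults to labels stored in `calls`.
#' @param subset antigen ids to restrict to (default: all).
#' @return A data frame with one row per cohort: n, median, q25, q75,
#'   total_positive.
#' @export
breadth_summary <- function(calls, labels = NULL, subset = NULL) {
  stopifnot(inherits(calls, "sero_calls"))
  if (is.null(labels)) labels <- calls$cohort
  labels <- as.character(labels)
  pos <- calls$positive
  if (!is.null(subset)) {
    missing_ag <- setdiff(subset, colnames(pos))
    if (length(missing_ag) > 0L) {
      stop(sprintf("subset antigen(s) not in calls: %s",
                   paste(head(missing_ag, 10L), collapse = ", ")),
           call. = FALSE)
    }
    pos <- pos[, subset, drop = FALSE]
  }
  counts <- rowSums(pos)
  out <- do.call(rbind, lapply(split(counts, labels), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), median = q[2L], q25 = q[1L], q75 = q[3L],
               total_positive = sum(v))
  }))
  out <- cbind(data.frame(cohort = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
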