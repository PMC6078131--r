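#' Intra-array normalisation by the overall array median
#'
#' Divides every intensity on an array by that array's overall median
#' across antigens (control spots, identified by `control_prefix`, are
#' excluded from the median but still divided). After the operation every
#' array's median over non-control antigens equals 1, removing
#' multiplicative scale differences between arrays.
#'
#' @param x an `intensity_matrix` of collapsed (median-of-replicates)
#'   intensities.
#' @param control_prefix regular expression identifying control-spot
#'   antigen ids to exclude from the median.
#' @return The normalised `intensity_matrix` with `"intra_median"` appended
#'   to its `normalization` record.
#' @export
intra_array_normalize <- function(x, control_prefix = "^CTRL") {
  stopifnot(inherits(x, "intensity_matrix"))
  keep <- !grepl(control_prefix, colnames(x$intensity))
  if (!any(keep)) {
    stop("no non-control antigens to compute the array median", call. = FALSE)
  }
  med <- apply(x$intensity[, keep, drop = FALSE], 1L, stats::median)
  bad <- !is.finite(med) | med <= 0
  if (any(bad)) {
    stop(sprintf("degenerate array(s) with non-positive overall median: %s",
                 paste(head(rownames(x$intensity)[bad], 10L), collapse = ", ")),
         call. = FALSE)
  }
  x$intensity <- x$intensity / med
  x$normalization <- c(x$normalization, "intra_median")
  x
}

#' Quantile normalisation across arrays
#'
#' Classic quantile normalisation: within each sample, values are replaced
#' by the mean of same-rank values across all samples (ties receive the
#' average of the tied quantile means), so that afterwards every sample
#' shares an identical intensity distribution while within-sample ranks
#' are preserved. Delegates to [limma::normalizeQuantiles()] with tie
#' averaging; the operation is idempotent.
#'
#' @param x an `intensity_matrix` with no missing values.
#' @return The normalised `intensity_matrix` with `"quantile"` appended to
#'   its `normalization` record.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (anyNA(x$intensity)) {
    stop("intensity matrix contains missing values", call. = FALSE)
  }
  m <- t(limma::normalizeQuantiles(t(x$intensity), ties = TRUE))
  dimnames(m) <- dimnames(x$intensity)
  x$intensity <- m
  x$normalization <- c(x$normalization, "quantile")
  x
}

#' Run the full normalisation pipeline on a spot-level dataset
#'
#' Fixed order: background subtraction, replicate collapse, QC exclusion
#' (when a reference serum is available), intra-array median division,
#' then quantile normalisation. The order matters — swapping the intra-
#' array and quantile steps changes the result — so the applied steps are
#' recorded in the `normalization` field of the returned matrix.
#'
#' @param dataset a `spot_dataset` (may include reference arrays).
#' @param reference optional reference `spot_dataset` to append before QC.
#' @param min_rho,max_cv QC thresholds, see [qc_arrays()].
#' @param skip_quantile skip the inter-array quantile step.
#' @param control_prefix control-spot antigen id pattern.
#' @return An `intensity_matrix` with an attached `$qc` report (or NULL
#'   when no reference serum was available).
#' @export
normalize_arrays <- function(dataset, reference = NULL, min_rho = 0.5,
                             max_cv = 0.5, skip_quantile = FALSE,
                             control_prefix = "^CTRL") {
  stopifnot(inherits(dataset, "spot_dataset"))
  if (!is.null(reference)) {
    dataset <- bind_spot_datasets(dataset, reference)
  }
  dataset <- subtract_background(dataset)
  x <- collapse_replicates(dataset)
  if (!is.null(x$reference)) {
    report <- qc_arrays(x, min_rho = min_rho, max_cv = max_cv,
                        spots = dataset)
    x <- drop_failed_arrays(x, report)
    x$qc <- report
  } else {
    x$qc <- NULL
  }
  x <- intra_array_normalize(x, control_prefix = control_prefix)
  if (!skip_quantile) {
    x <- quantile_normalize(x)
  }
  x
}
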