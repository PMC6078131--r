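## Spot-table schema (tab-delimited text, GPR-like):
##   # seroscreen spot-table v1
##   array_id antigen_id replicate_idx rfu background_rfu [cohort] [batch]
## Antigen ids matching the control-spot prefix (default "CTRL") are control
## spots: kept in the matrix but excluded from the intra-array median.

SPOT_TABLE_SCHEMA <- "seroscreen spot-table v1"
REQUIRED_SPOT_COLS <- c("array_id", "antigen_id", "replicate_idx",
                        "rfu", "background_rfu")

#' Write a spot-level dataset as a tab-delimited text table
#'
#' Sample metadata (cohort, batch) is written as extra columns so that the
#' file round-trips through [read_spot_table()].
#'
#' @param dataset a `spot_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "spot_dataset"))
  meta <- dataset$samples[match(dataset$spots$array_id,
                                dataset$samples$array_id), ]
  out <- cbind(dataset$spots,
               cohort = meta$cohort, batch = meta$batch)
  writeLines(c(paste0("# ", SPOT_TABLE_SCHEMA),
               paste(colnames(out), collapse = "\t")), path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth a `ground_truth` object from [generate_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(
    planted = truth$planted,
    spike_prob = truth$spike_prob,
    indicator = as.data.frame(cbind(
      data.frame(array_id = rownames(truth$indicator)),
      as.data.frame(truth$indicator)
    )),
    samples = truth$samples
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Read a spot-level table
#'
#' Parses the tab-delimited spot schema written by [write_spot_table()]
#' (leading `#` comment lines are skipped). Rows with non-numeric `rfu`,
#' `background_rfu` or `replicate_idx` are reported with their line
#' numbers: by default parsing stops; with `lenient = TRUE` they are
#' dropped with a warning.
#'
#' @param path input file path.
#' @param lenient drop malformed rows with a warning instead of erroring.
#' @return A `spot_dataset`.
#' @export
read_spot_table <- function(path, lenient = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 100L)
  n_comment <- 0L
  while (n_comment < length(first) && startsWith(first[n_comment + 1L], "#")) {
    n_comment <- n_comment + 1L
  }
  dt <- data.table::fread(path, sep = "\t", skip = n_comment, header = TRUE,
                          colClasses = "character", fill = TRUE,
                          data.table = TRUE)
  missing_cols <- setdiff(REQUIRED_SPOT_COLS, colnames(dt))
  if (length(missing_cols) > 0L) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(sQuote(missing_cols), collapse = ", ")),
         call. = FALSE)
  }
  num <- suppressWarnings(list(
    replicate_idx = as.numeric(dt$replicate_idx),
    rfu = as.numeric(dt$rfu),
    background_rfu = as.numeric(dt$background_rfu)
  ))
  bad <- !is.finite(num$rfu) | !is.finite(num$background_rfu) |
    !is.finite(num$replicate_idx) | is.na(dt$array_id) | dt$array_id == ""
  if (any(bad)) {
    ## line number in the file: comments + header + data row index
    lines <- which(bad) + n_comment + 1L
    msg <- sprintf("%d malformed row(s) at line(s) %s", sum(bad),
                   paste(head(lines, 10L), collapse = ", "))
    if (!lenient) {
      stop(sprintf("parse error: %s", msg), call. = FALSE)
    }
    warning(msg, call. = FALSE)
  }
  keep <- !bad
  spots <- data.frame(
    array_id = dt$array_id[keep],
    antigen_id = dt$antigen_id[keep],
    replicate_idx = as.integer(num$replicate_idx[keep]),
    rfu = num$rfu[keep],
    background_rfu = num$background_rfu[keep],
    stringsAsFactors = FALSE
  )
  has_cohort <- "cohort" %in% colnames(dt)
  samp_src <- data.frame(
    array_id = dt$array_id[keep],
    cohort = if (has_cohort) dt$cohort[keep] else NA_character_,
    batch = if ("batch" %in% colnames(dt)) dt$batch[keep] else "batch01",
    stringsAsFactors = FALSE
  )
  samples <- unique(samp_src)
  samples$sample_id <- samples$array_id
  samples$qc_corrupted <- FALSE
  samples <- samples[, c("array_id", "sample_id", "cohort", "batch",
                         "qc_corrupted")]
  rownames(samples) <- NULL
  if (has_cohort) {
    ok <- samples$cohort %in% c("patient", "control", "reference")
    if (!all(ok)) {
      stop(sprintf("format error: invalid cohort label(s) %s",
                   paste(sQuote(unique(samples$cohort[!ok])), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(spots = spots, samples = samples), class = "spot_dataset")
}

#' Subtract the local spot background from foreground intensities
#'
#' `rfu` becomes `max(rfu - background_rfu, 0)` (negative fluorescence is
#' non-physical and would break the positive-median precondition of
#' intra-array normalisation); the background column is zeroed.
#'
#' @param dataset a `spot_dataset`.
#' @return The background-subtracted `spot_dataset`.
#' @export
subtract_background <- function(dataset) {
  stopifnot(inherits(dataset, "spot_dataset"))
  dataset$spots$rfu <- pmax(dataset$spots$rfu - dataset$spots$background_rfu, 0)
  dataset$spots$background_rfu <- 0
  dataset
}

new_intensity_matrix <- function(intensity, cohort, batch = NULL,
                                 reference = NULL,
                                 normalization = character()) {
  structure(list(intensity = intensity, cohort = cohort, batch = batch,
                 reference = reference, normalization = normalization),
            class = "intensity_matrix")
}

#' Collapse replicate spots to one median intensity per (sample, antigen)
#'
#' Each cell of the resulting matrix is the median of the replicate rfu
#' values (for quadruplicates, the mean of the two central readings).
#' Reference arrays are excluded from the analysis matrix but retained in
#' the `$reference` slot for QC.
#'
#' @param dataset a background-subtracted `spot_dataset`.
#' @return An `intensity_matrix`: `$intensity` (samples x antigens),
#'   `$cohort` (named vector), `$reference` (matrix or NULL),
#'   `$normalization` (steps applied so far).
#' @export
collapse_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "spot_dataset"))
  dt <- data.table::as.data.table(dataset$spots)
  agg <- dt[, list(value = stats::median(rfu)), by = c("array_id", "antigen_id")]
  arrays <- unique(agg$array_id)
  antigens <- sort(unique(agg$antigen_id))
  per_antigen <- agg[, list(N = .N), by = "antigen_id"]
  incomplete <- per_antigen$antigen_id[per_antigen$N < length(arrays)]
  if (length(incomplete) > 0L) {
    stop(sprintf("antigen(s) missing replicates on some arrays: %s",
                 paste(head(incomplete, 10L), collapse = ", ")),
         call. = FALSE)
  }
  wide <- data.table::dcast(agg, array_id ~ antigen_id, value.var = "value")
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$array_id
  m <- m[, antigens, drop = FALSE]

  samples <- dataset$samples
  samples <- samples[match(intersect(samples$array_id, rownames(m)),
                           samples$array_id), ]
  m <- m[samples$array_id, , drop = FALSE]
  is_ref <- !is.na(samples$cohort) & samples$cohort == "reference"
  reference <- if (any(is_ref)) m[samples$array_id[is_ref], , drop = FALSE]
  analysis <- m[samples$array_id[!is_ref], , drop = FALSE]
  cohort <- samples$cohort[!is_ref]
  names(cohort) <- samples$array_id[!is_ref]
  batch <- samples$batch[!is_ref]
  names(batch) <- names(cohort)
  new_intensity_matrix(analysis, cohort, batch = batch,
                       reference = if (any(is_ref)) reference else NULL)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "intensity_matrix: %d samples x %d antigens (%s)\n",
    nrow(x$intensity), ncol(x$intensity),
    if (length(x$normalization)) {
      paste("normalised:", paste(x$normalization, collapse = " -> "))
    } else "raw"
  ))
  invisible(x)
}

#' Quality-control arrays against a reference serum
#'
#' Each array is compared with the reference serum by Spearman rank
#' correlation across antigens; arrays with `rho < min_rho` fail. If the
#' spot-level dataset is supplied, the median replicate coefficient of
#' variation (sd/mean over replicate spots) is also computed and arrays
#' with `median CV > max_cv` fail.
#'
#' @param x an `intensity_matrix` (pre-normalisation).
#' @param reference reference intensities: a named vector or 1-row matrix;
#'   defaults to `x$reference`.
#' @param min_rho minimum Spearman correlation versus the reference.
#' @param max_cv maximum median replicate coefficient of variation.
#' @param spots optional `spot_dataset` for the replicate-CV criterion.
#' @return A `qc_report` data frame: array_id, rho, median_cv, pass, reason.
#' @export
qc_arrays <- function(x, reference = NULL, min_rho = 0.5, max_cv = 0.5,
                      spots = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (is.null(reference)) reference <- x$reference
  if (is.null(reference)) {
    stop("no reference serum available for QC", call. = FALSE)
  }
  if (is.matrix(reference)) reference <- reference[1L, ]
  if (ncol(x$intensity) < 3L) {
    stop("fewer than 3 antigens: cannot compute rank correlation",
         call. = FALSE)
  }
  ref <- reference[colnames(x$intensity)]
  if (anyNA(ref)) {
    stop("reference serum does not cover all antigens", call. = FALSE)
  }
  rho <- apply(x$intensity, 1L, function(r) {
    suppressWarnings(cor(r, ref, method = "spearman"))
  })
  med_cv <- rep(NA_real_, nrow(x$intensity))
  names(med_cv) <- rownames(x$intensity)
  if (!is.null(spots)) {
    dt <- data.table::as.data.table(spots$spots)
    cv <- dt[, list(value = {
      m <- mean(rfu)
      if (is.finite(m) && m > 0 && .N > 1L) sd(rfu) / m else NA_real_
    }), by = c("array_id", "antigen_id")]
    per_arr <- cv[, list(value = stats::median(value, na.rm = TRUE)),
                  by = "array_id"]
    med_cv[per_arr$array_id[per_arr$array_id %in% names(med_cv)]] <-
      per_arr$value[per_arr$array_id %in% names(med_cv)]
  }
  fail_rho <- is.na(rho) | rho < min_rho
  fail_cv <- !is.na(med_cv) & med_cv > max_cv
  reason <- character(length(rho))
  reason[fail_rho] <- sprintf("spearman rho < %g", min_rho)
  reason[fail_cv] <- trimws(paste(reason[fail_cv],
                                  sprintf("median replicate CV > %g", max_cv),
                                  sep = "; "))
  reason[fail_cv & !fail_rho] <- sprintf("median replicate CV > %g", max_cv)
  report <- data.frame(
    array_id = rownames(x$intensity),
    rho = unname(rho),
    median_cv = unname(med_cv),
    pass = !(fail_rho | fail_cv),
    reason = reason,
    stringsAsFactors = FALSE
  )
  attr(report, "min_rho") <- min_rho
  attr(report, "max_cv") <- max_cv
  class(report) <- c("qc_report", "data.frame")
  report
}

#' Drop arrays that failed quality control
#'
#' @param x an `intensity_matrix`.
#' @param report a `qc_report` from [qc_arrays()].
#' @return The filtered `intensity_matrix`.
#' @export
drop_failed_arrays <- function(x, report) {
  stopifnot(inherits(x, "intensity_matrix"))
  keep <- report$array_id[report$pass]
  keep <- intersect(rownames(x$intensity), keep)
  x$intensity <- x$intensity[keep, , drop = FALSE]
  x$cohort <- x$cohort[keep]
  x$batch <- x$batch[keep]
  x
}
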