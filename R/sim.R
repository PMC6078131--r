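#' Configuration for the synthetic serology cohort generator
#'
#' Bundles every parameter of the simulated study: cohort sizes, array
#' layout, the lognormal intensity model, and the planted seroreactive
#' antigens that provide ground truth for recovery tests.
#'
#' The intensity model is multiplicative on the log scale. Each antigen
#' receives a baseline drawn once from
#' `Lognormal(background_log_mean, antigen_log_sd)` and shared across all
#' arrays, which produces the right-skewed, heavy-tailed spot intensities
#' typical of serology arrays. Each array carries a multiplicative scale
#' factor (`batch_log_sd`) so that intra-array normalisation is
#' non-trivial, each (sample, antigen) cell adds independent lognormal
#' noise (`background_log_sd`), and each replicate spot adds smaller
#' lognormal noise (`replicate_log_sd`). A planted antigen in a "positive"
#' sample (latent Bernoulli draw) is multiplied by a lognormal spike factor
#' (`spike_log_mean`, `spike_log_sd`), mirroring the positive/negative
#' seroreactivity semantics used downstream.
#'
#' @param n_antigens number of antigens printed on the array.
#' @param n_patients,n_controls cohort sizes (one array per sample).
#' @param n_planted number of truly patient-biased antigens (may be 0 for
#'   a null cohort).
#' @param spike_prob_patient probability that a patient is seroreactive
#'   for a planted antigen.
#' @param spike_prob_control background seroreactivity probability for a
#'   planted antigen in controls.
#' @param spike_log_mean,spike_log_sd log-scale mean and sd of the
#'   multiplicative intensity spike for positive reactions.
#' @param background_log_mean log-scale mean rfu of the antigen baseline.
#' @param background_log_sd log-scale sd of per-(sample, antigen) noise.
#' @param antigen_log_sd log-scale sd of the per-antigen baseline.
#' @param batch_log_sd log-scale sd of the per-array scale factor.
#' @param replicate_log_sd log-scale sd of per-spot replicate noise.
#' @param spot_background_log_mean,spot_background_log_sd lognormal
#'   parameters of the local spot background (rfu).
#' @param n_replicates spots per antigen per array (quadruplicate default).
#' @param qc_fail_rate probability an array is corrupted (see
#'   [inject_qc_failures()]).
#' @param seed integer random seed; identical configurations yield
#'   bit-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_cohort()], [generate_reference_serum()]
#' @export
#' @examples
#' cfg <- sim_config(n_antigens = 50, n_patients = 10, n_controls = 10,
#'                   n_planted = 3, seed = 1)
sim_config <- function(n_antigens = 1627L,
                       n_patients = 104L,
                       n_controls = 105L,
                       n_planted = 15L,
                       spike_prob_patient = 0.15,
                       spike_prob_control = 0.02,
                       spike_log_mean = log(20),
                       spike_log_sd = 0.6,
                       background_log_mean = 7,
                       background_log_sd = 0.8,
                       antigen_log_sd = 1.2,
                       batch_log_sd = 0.2,
                       replicate_log_sd = 0.1,
                       spot_background_log_mean = log(100),
                       spot_background_log_sd = 0.3,
                       n_replicates = 4L,
                       qc_fail_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_antigens = as.integer(n_antigens), n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls), n_planted = as.integer(n_planted),
    spike_prob_patient = spike_prob_patient,
    spike_prob_control = spike_prob_control,
    spike_log_mean = spike_log_mean, spike_log_sd = spike_log_sd,
    background_log_mean = background_log_mean,
    background_log_sd = background_log_sd,
    antigen_log_sd = antigen_log_sd, batch_log_sd = batch_log_sd,
    replicate_log_sd = replicate_log_sd,
    spot_background_log_mean = spot_background_log_mean,
    spot_background_log_sd = spot_background_log_sd,
    n_replicates = as.integer(n_replicates),
    qc_fail_rate = qc_fail_rate, seed = as.integer(seed)
  )
  .chk_field(cfg$n_antigens >= 1L, "n_antigens", "must be a positive count")
  .chk_field(cfg$n_patients >= 1L, "n_patients", "must be a positive count")
  .chk_field(cfg$n_controls >= 1L, "n_controls", "must be a positive count")
  .chk_field(cfg$n_replicates >= 1L, "n_replicates",
             "must be a positive count")
  .chk_field(cfg$n_planted >= 0L, "n_planted", "must be a non-negative count")
  .chk_field(cfg$n_planted <= cfg$n_antigens, "n_planted",
             "cannot exceed n_antigens")
  for (f in c("spike_prob_patient", "spike_prob_control", "qc_fail_rate")) {
    .chk_field(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L &&
                 cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
  }
  if (cfg$n_planted > 0L) {
    .chk_field(cfg$spike_prob_patient > cfg$spike_prob_control,
               "spike_prob_patient",
               "must exceed spike_prob_control for planted antigens")
  }
  for (f in c("spike_log_sd", "background_log_sd", "antigen_log_sd",
              "batch_log_sd", "replicate_log_sd", "spot_background_log_sd")) {
    .chk_field(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f,
               "must be a non-negative sd")
  }
  .chk_field(!is.na(cfg$seed), "seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

.chk_field <- function(cond, field, msg) {
  if (!isTRUE(cond)) {
    stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  }
}

## Per-antigen lognormal baselines, drawn deterministically from the config
## seed so that cohort and reference serum share the same array layout.
.antigen_baselines <- function(config) {
  set.seed(config$seed)
  b <- exp(config$background_log_mean +
             rnorm(config$n_antigens, 0, config$antigen_log_sd))
  names(b) <- sprintf("AG%05d", seq_len(config$n_antigens))
  b
}

.expand_spots <- function(latent_log, sample_ids, antigens, config) {
  n_s <- length(sample_ids)
  n_a <- length(antigens)
  n_r <- config$n_replicates
  n <- n_s * n_a * n_r
  ## latent_log is samples x antigens; expand sample-major, antigen, replicate
  lat <- rep(as.vector(t(latent_log)), each = n_r)
  signal <- exp(lat + rnorm(n, 0, config$replicate_log_sd))
  bg <- exp(rnorm(n, config$spot_background_log_mean,
                  config$spot_background_log_sd))
  data.frame(
    array_id = rep(sample_ids, each = n_a * n_r),
    antigen_id = rep(rep(antigens, each = n_r), times = n_s),
    replicate_idx = rep(seq_len(n_r), times = n_s * n_a),
    rfu = signal + bg,
    background_rfu = bg,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic spot-level cohort with known ground truth
#'
#' Simulates one array per sample under the model described in
#' [sim_config()]: antigens in quadruplicate (or `n_replicates`), lognormal
#' backgrounds, a per-array scale factor, and a set of planted antigens
#' whose positive samples receive a multiplicative intensity spike.
#' Patients are positive for a planted antigen with probability
#' `spike_prob_patient`, controls with `spike_prob_control`.
#'
#' @param config a [sim_config()] object.
#' @param cohort_seed optional integer seed for the sample-level draws
#'   only. The array platform (per-antigen baselines and the planted
#'   antigen set) is always derived from `config$seed`, so two calls with
#'   the same config but different `cohort_seed` yield independent
#'   cohorts screened on the same array with the same true biomarkers —
#'   e.g. a discovery and a validation cohort.
#' @return A list with components
#'   \describe{
#'     \item{dataset}{a `spot_dataset`: `$spots` (array_id, antigen_id,
#'       replicate_idx, rfu, background_rfu) and `$samples` (array_id,
#'       sample_id, cohort, batch, qc_corrupted).}
#'     \item{truth}{a `ground_truth`: planted antigen ids, their true
#'       per-cohort spike probabilities, and the n_samples x n_planted
#'       positivity indicator matrix.}
#'   }
#' @export
generate_cohort <- function(config, cohort_seed = NULL) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be created by sim_config()", call. = FALSE)
  }
  baselines <- .antigen_baselines(config)  # seeds the RNG
  antigens <- names(baselines)
  planted <- if (config$n_planted > 0L) {
    sort(sample(antigens, config$n_planted))
  } else {
    character(0)
  }
  if (!is.null(cohort_seed)) set.seed(as.integer(cohort_seed))
  n_p <- config$n_patients
  n_c <- config$n_controls
  n_s <- n_p + n_c
  sample_ids <- c(sprintf("PAT%04d", seq_len(n_p)),
                  sprintf("CTL%04d", seq_len(n_c)))
  cohort <- rep(c("patient", "control"), c(n_p, n_c))

  array_scale_log <- rnorm(n_s, 0, config$batch_log_sd)
  latent <- matrix(rnorm(n_s * config$n_antigens, 0, config$background_log_sd),
                   n_s, config$n_antigens,
                   dimnames = list(sample_ids, antigens))
  latent <- sweep(latent, 2, log(baselines), "+")
  latent <- latent + array_scale_log  # recycles down rows

  indicator <- matrix(0L, n_s, length(planted),
                      dimnames = list(sample_ids, planted))
  if (length(planted) > 0L) {
    p_row <- ifelse(cohort == "patient",
                    config$spike_prob_patient, config$spike_prob_control)
    indicator[] <- rbinom(n_s * length(planted), 1L,
                          rep(p_row, times = length(planted)))
    n_hit <- sum(indicator)
    if (n_hit > 0L) {
      spikes <- rnorm(n_hit, config$spike_log_mean, config$spike_log_sd)
      sub <- latent[, planted, drop = FALSE]
      sub[indicator == 1L] <- sub[indicator == 1L] + spikes
      latent[, planted] <- sub
    }
  }

  spots <- .expand_spots(latent, sample_ids, antigens, config)
  samples <- data.frame(
    array_id = sample_ids, sample_id = sample_ids, cohort = cohort,
    batch = "batch01", qc_corrupted = FALSE, stringsAsFactors = FALSE
  )
  dataset <- structure(list(spots = spots, samples = samples),
                       class = "spot_dataset")
  if (config$qc_fail_rate > 0) {
    dataset <- inject_qc_failures(dataset, config$qc_fail_rate,
                                  seed = config$seed + 4099L)
  }
  truth <- structure(list(
    planted = planted,
    spike_prob = data.frame(
      antigen_id = planted,
      patient = rep(config$spike_prob_patient, length(planted)),
      control = rep(config$spike_prob_control, length(planted)),
      stringsAsFactors = FALSE
    ),
    indicator = indicator,
    samples = dataset$samples[, c("array_id", "cohort")]
  ), class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Corrupt a random subset of arrays to emulate QC failures
#'
#' Flagged arrays have every spot intensity replaced by uncorrelated
#' lognormal noise (moments matched to the dataset as a whole), destroying
#' the antigen structure so that reference-serum QC can detect them.
#'
#' @param dataset a `spot_dataset`.
#' @param rate probability in \[0, 1\] that each array is corrupted.
#' @param seed integer seed for the corruption draw.
#' @return The dataset with corrupted intensities and
#'   `samples$qc_corrupted` flags updated.
#' @export
inject_qc_failures <- function(dataset, rate, seed = 1L) {
  stopifnot(inherits(dataset, "spot_dataset"))
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop("'rate' must be in [0, 1]", call. = FALSE)
  }
  if (rate == 0) {
    return(dataset)
  }
  set.seed(seed)
  flag <- runif(nrow(dataset$samples)) < rate
  if (rate >= 1) flag[] <- TRUE
  corrupt <- dataset$samples$array_id[flag]
  idx <- dataset$spots$array_id %in% corrupt
  if (any(idx)) {
    lr <- log(pmax(dataset$spots$rfu, 1e-8))
    dataset$spots$rfu[idx] <- exp(rnorm(sum(idx), mean(lr), sd(lr)))
  }
  dataset$samples$qc_corrupted <- dataset$samples$qc_corrupted | flag
  dataset
}

#' Generate the reference serum array for a simulated run
#'
#' Draws one array from the background model (no spikes) using the same
#' per-antigen baselines as [generate_cohort()] for the same config, so it
#' rank-correlates with clean cohort arrays but not with corrupted ones.
#' Stored under the reserved sample id `REF0001` with cohort label
#' `"reference"`.
#'
#' @param config a [sim_config()] object.
#' @return A `spot_dataset` containing the single reference array.
#' @export
generate_reference_serum <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be created by sim_config()", call. = FALSE)
  }
  baselines <- .antigen_baselines(config)
  set.seed(config$seed + 7919L)
  latent <- matrix(log(baselines) +
                     rnorm(config$n_antigens, 0, config$background_log_sd),
                   nrow = 1L,
                   dimnames = list("REF0001", names(baselines)))
  spots <- .expand_spots(latent, "REF0001", names(baselines), config)
  samples <- data.frame(
    array_id = "REF0001", sample_id = "REF0001", cohort = "reference",
    batch = "batch01", qc_corrupted = FALSE, stringsAsFactors = FALSE
  )
  structure(list(spots = spots, samples = samples), class = "spot_dataset")
}

#' Combine spot-level datasets (e.g. cohort plus reference serum)
#'
#' @param ... `spot_dataset` objects with disjoint array ids.
#' @return A single `spot_dataset`.
#' @export
bind_spot_datasets <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "spot_dataset")))
  ids <- unlist(lapply(parts, function(d) d$samples$array_id))
  if (anyDuplicated(ids)) {
    stop("duplicate array ids across datasets", call. = FALSE)
  }
  structure(list(
    spots = do.call(rbind, lapply(parts, `[[`, "spots")),
    samples = do.call(rbind, lapply(parts, `[[`, "samples"))
  ), class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  tab <- table(x$samples$cohort)
  cat(sprintf(
    "spot_dataset: %d arrays (%s), %d antigens, %d spot records\n",
    nrow(x$samples),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    length(unique(x$spots$antigen_id)), nrow(x$spots)
  ))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d planted antigens, %d samples\n",
              length(x$planted), nrow(x$samples)))
  invisible(x)
}
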