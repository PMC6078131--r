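# Shared fixture builders (everything is generated in code at test time).

small_sim <- function(seed = 1, ...) {
  args <- list(n_antigens = 60L, n_patients = 15L, n_controls = 15L,
               n_planted = 4L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# The recovery study conditions: 200 antigens, 15 planted, 100 + 100 samples
# with spike probabilities 0.15 (patients) / 0.02 (controls).
recovery_sim <- function(seed) {
  sim_config(n_antigens = 200L, n_patients = 100L, n_controls = 100L,
             n_planted = 15L, spike_prob_patient = 0.15,
             spike_prob_control = 0.02, seed = seed)
}

normalized_cohort <- function(config) {
  gen <- generate_cohort(config)
  ref <- generate_reference_serum(config)
  x <- normalize_arrays(gen$dataset, reference = ref)
  list(x = x, truth = gen$truth, reference = ref)
}

# A random seroreactivity-call fixture with no simulation machinery.
random_calls <- function(n = 12, p = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * p)), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("G%02d", 1:p)))
  labels <- sample(rep(c("patient", "control"), length.out = n))
  cutoffs <- data.frame(antigen_id = colnames(m),
                        cutoff = exp(rnorm(p, 0, 0.5)))
  pos <- sweep(m, 2, cutoffs$cutoff, ">")
  sc <- sweep(m, 2, cutoffs$cutoff, "/")
  sc[!pos] <- NA_real_
  calls <- structure(list(positive = pos, sc_ratio = sc, cutoffs = cutoffs,
                          cohort = stats::setNames(labels, rownames(m))),
                     class = "sero_calls")
  list(intensity = m, labels = labels, cutoffs = cutoffs, calls = calls)
}

# Hand-buildable forest-run stubs for aggregation tests.
fake_run <- function(ids, scores) {
  structure(list(seed = 0, mode = "regression",
                 importance = NULL,
                 top = data.frame(antigen_id = ids, importance = NA_real_,
                                  rank_score = scores,
                                  stringsAsFactors = FALSE)),
            class = "forest_run")
}
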