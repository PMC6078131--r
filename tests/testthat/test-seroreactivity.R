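test_that("cutoffs follow the Q75 + 2.5 x IQR rule with type-7 quantiles", {
  m <- matrix(1:8, 8, 1, dimnames = list(paste0("S", 1:8), "G1"))
  tab <- compute_cutoffs(m)
  expect_equal(tab$q75, 6.25)
  expect_equal(tab$iqr, 3.5)
  expect_equal(tab$cutoff, 15.0)

  const <- matrix(4.2, 6, 1, dimnames = list(paste0("S", 1:6), "G1"))
  ctab <- compute_cutoffs(const)
  expect_equal(ctab$iqr, 0)
  expect_equal(ctab$cutoff, 4.2)

  ## scale equivariance
  set.seed(3)
  r <- matrix(exp(rnorm(50)), 10, 5,
              dimnames = list(paste0("S", 1:10), paste0("G", 1:5)))
  t1 <- compute_cutoffs(r)
  t2 <- compute_cutoffs(r * 7)
  expect_equal(t2$cutoff, 7 * t1$cutoff, tolerance = 1e-12)

  expect_error(compute_cutoffs(r[1:3, , drop = FALSE]), "fewer than 4")
})

test_that("cutoff basis can be restricted to controls and is recorded", {
  fx <- random_calls(n = 20, p = 4, seed = 8)
  t_all <- compute_cutoffs(fx$intensity, labels = fx$labels)
  t_ctl <- compute_cutoffs(fx$intensity, basis = "controls",
                           labels = fx$labels)
  expect_identical(attr(t_all, "basis"), "all")
  expect_identical(attr(t_ctl, "basis"), "controls")
  oracle <- apply(fx$intensity[fx$labels == "control", ], 2, function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] + 2.5 * (q[2] - q[1])
  })
  expect_equal(t_ctl$cutoff, unname(oracle))
})

test_that("dichotomisation is strictly above-cutoff with S/C ratios", {
  m <- matrix(c(30, 15, 10), 3, 1,
              dimnames = list(c("hi", "at", "lo"), "G1"))
  cut <- data.frame(antigen_id = "G1", cutoff = 15)
  calls <- dichotomize(m, cut)
  expect_equal(unname(calls$positive[, 1]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(calls$sc_ratio[, 1]), c(2, NA, NA))
  expect_true(all(calls$sc_ratio > 1, na.rm = TRUE))

  expect_error(dichotomize(m, data.frame(antigen_id = "other", cutoff = 1)),
               "G1")
  zero_cut <- data.frame(antigen_id = "G1", cutoff = 0)
  expect_warning(z <- dichotomize(m, zero_cut), "unscorable")
  expect_equal(ncol(z$positive), 0L)
})

test_that("null-cohort positivity matches a Monte-Carlo tail oracle", {
  cfg <- small_sim(seed = 21, n_antigens = 120L, n_patients = 30L,
                   n_controls = 30L, n_planted = 0L,
                   spike_prob_patient = 0, spike_prob_control = 0)
  nc <- normalized_cohort(cfg)
  calls <- dichotomize(nc$x, compute_cutoffs(nc$x))
  observed <- mean(calls$positive)

  ## independent oracle: expected in-sample tail mass beyond Q75 + 2.5 IQR
  ## for the generator's lognormal per-(sample, antigen) noise
  set.seed(99)
  n <- nrow(nc$x$intensity)
  mc <- replicate(400, {
    v <- exp(rnorm(n, 0, cfg$background_log_sd))
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    mean(v > q[2] + 2.5 * (q[2] - q[1]))
  })
  expect_lt(abs(observed - mean(mc)), 0.015)
})

test_that("biomarker scores follow the N_pos x cube-root(mean S/C) rule", {
  ## 8 patient positives with mean S/C 8 -> 8 * 2 = 16; no control positives
  pos <- matrix(FALSE, 10, 1, dimnames = list(paste0("S", 1:10), "G1"))
  pos[1:8, 1] <- TRUE
  sc <- matrix(NA_real_, 10, 1, dimnames = dimnames(pos))
  sc[1:8, 1] <- 8
  calls <- structure(list(positive = pos, sc_ratio = sc,
                          cutoffs = data.frame(antigen_id = "G1", cutoff = 1),
                          cohort = NULL), class = "sero_calls")
  labels <- c(rep("patient", 8), rep("control", 2))
  tab <- biomarker_scores(calls, labels)
  expect_equal(tab$score_patient, 16)
  expect_equal(tab$score_control, 0)
  expect_equal(tab$score_diff, 16)
  expect_equal(tab$sensitivity, 1)
  expect_equal(tab$specificity, 1)

  ## 3 positives with S/C {2, 2, 16}: 3 * (20/3)^(1/3)
  sc2 <- sc
  pos2 <- pos
  pos2[, 1] <- c(rep(TRUE, 3), rep(FALSE, 7))
  sc2[, 1] <- c(2, 2, 16, rep(NA, 7))
  calls2 <- structure(list(positive = pos2, sc_ratio = sc2,
                           cutoffs = data.frame(antigen_id = "G1",
                                                cutoff = 1),
                           cohort = NULL), class = "sero_calls")
  tab2 <- biomarker_scores(calls2, labels)
  expect_equal(tab2$score_patient, 3 * (20 / 3)^(1 / 3), tolerance = 1e-12)
  expect_equal(round(tab2$score_patient, 3), 5.646)

  expect_error(biomarker_scores(calls2, rep("case", 10)), "case")
})

test_that("biomarker scores equal the naive double-loop oracle", {
  for (s in 1:10) {
    fx <- random_calls(n = 30, p = 20, seed = 500 + s)
    tab <- biomarker_scores(fx$calls, fx$labels)
    oracle <- oracle_biomarker_scores(fx$intensity, fx$cutoffs, fx$labels)
    oracle <- oracle[match(tab$antigen_id, oracle$antigen_id), ]
    expect_equal(tab$score_patient, oracle$score_patient, tolerance = 1e-12)
    expect_equal(tab$score_control, oracle$score_control, tolerance = 1e-12)
    expect_equal(tab$score_diff, oracle$score_diff, tolerance = 1e-12)
    expect_equal(tab$sensitivity, oracle$sensitivity)
    expect_equal(tab$specificity, oracle$specificity)
  }
})

test_that("cohort swap negates the score difference", {
  fx <- random_calls(n = 24, p = 10, seed = 77)
  tab <- biomarker_scores(fx$calls, fx$labels)
  swapped <- ifelse(fx$labels == "patient", "control", "patient")
  tab2 <- biomarker_scores(fx$calls, swapped)
  expect_equal(tab2$score_diff, -tab$score_diff, tolerance = 1e-12)
})

test_that("raising one positive patient intensity never lowers the score", {
  fx <- random_calls(n = 20, p = 5, seed = 31)
  i_pat <- which(fx$labels == "patient")[1]
  m1 <- fx$intensity
  m1[i_pat, 1] <- fx$cutoffs$cutoff[1] * 2  # ensure a positive patient call
  base <- biomarker_scores(dichotomize(m1, fx$cutoffs), fx$labels)
  m2 <- m1
  m2[i_pat, 1] <- m1[i_pat, 1] * 10
  tab2 <- biomarker_scores(dichotomize(m2, fx$cutoffs), fx$labels)
  expect_gt(tab2$score_patient[1], base$score_patient[1])
  expect_gt(tab2$score_diff[1], base$score_diff[1])
})

test_that("candidate selection is a strict ordered filter", {
  tab <- data.frame(antigen_id = c("B", "A", "C"),
                    score_diff = c(6, 5, 4.9))
  expect_identical(select_candidates(tab, 5), "B")
  expect_identical(select_candidates(tab, -Inf), c("B", "A", "C"))
  tie <- data.frame(antigen_id = c("Z", "A"), score_diff = c(7, 7))
  expect_identical(select_candidates(tie, 5), c("A", "Z"))
})

test_that("serum scores sum full intensities above cutoffs", {
  m <- matrix(c(20, 5), 1, 2, dimnames = list("S1", c("G1", "G2")))
  cut <- data.frame(antigen_id = c("G1", "G2"), cutoff = c(10, 10))
  ss <- serum_scores(m, cut)
  expect_equal(ss$samples$serum_score, 20)
  expect_equal(ss$samples$n_positive, 1)

  none <- serum_scores(matrix(c(1, 1), 1, 2,
                              dimnames = list("S1", c("G1", "G2"))), cut)
  expect_equal(none$samples$serum_score, 0)
  expect_equal(none$samples$n_positive, 0)

  expect_error(serum_scores(m, cut, subset = character(0)), "empty")
})

test_that("serum scores are additive over disjoint subsets", {
  fx <- random_calls(n = 15, p = 8, seed = 13)
  a <- colnames(fx$intensity)[1:3]
  b <- colnames(fx$intensity)[4:8]
  s_a <- serum_scores(fx$intensity, fx$cutoffs, subset = a)
  s_b <- serum_scores(fx$intensity, fx$cutoffs, subset = b)
  s_ab <- serum_scores(fx$intensity, fx$cutoffs, subset = c(a, b))
  expect_equal(s_ab$samples$serum_score,
               s_a$samples$serum_score + s_b$samples$serum_score,
               tolerance = 1e-12)
  ## restriction never increases a sample's score
  expect_true(all(s_a$samples$serum_score <= s_ab$samples$serum_score))
})

test_that("breadth summary counts positives and conserves totals", {
  fx <- random_calls(n = 20, p = 10, seed = 55)
  br <- breadth_summary(fx$calls, fx$labels)
  expect_equal(sum(br$total_positive), sum(fx$calls$positive))

  sub <- colnames(fx$calls$positive)[1:4]
  br_sub <- breadth_summary(fx$calls, fx$labels, subset = sub)
  expect_equal(sum(br_sub$total_positive), sum(fx$calls$positive[, sub]))

  empty_calls <- fx$calls
  empty_calls$positive[] <- FALSE
  br0 <- breadth_summary(empty_calls, fx$labels)
  expect_true(all(br0$median == 0))
})
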