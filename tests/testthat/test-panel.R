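test_that("run_forest validates inputs and ranks deterministically", {
  fx <- random_calls(n = 20, p = 5, seed = 91)
  r1 <- run_forest(fx$intensity, fx$labels, n_trees = 50, seed = 3)
  r2 <- run_forest(fx$intensity, fx$labels, n_trees = 50, seed = 3)
  expect_identical(r1$importance, r2$importance)
  ## 5 features: rank scores keep the 20 = best anchor
  expect_equal(r1$top$rank_score, c(20, 19, 18, 17, 16))

  expect_error(run_forest(fx$intensity, rep("patient", 20), n_trees = 10),
               "degenerate")
  expect_error(run_forest(fx$intensity[, 1, drop = FALSE], fx$labels,
                          n_trees = 10), "2 candidate")
})

test_that("a perfectly separating antigen dominates the top rank", {
  set.seed(17)
  n <- 100
  labels <- rep(c("patient", "control"), each = n / 2)
  m <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("G%02d", 1:10)))
  m[, "G03"] <- ifelse(labels == "patient", 5, 0) + rnorm(n, 0, 0.1)
  hits <- sum(vapply(1:20, function(s) {
    run_forest(m, labels, n_trees = 100, seed = s)$top$antigen_id[1] == "G03"
  }, logical(1)))
  expect_gte(hits, 19)
})

test_that("rank aggregation matches the brute-force tally", {
  runs <- list(
    fake_run(c("A", "B", "C"), c(20, 19, 18)),
    fake_run(c("B", "A", "D"), c(20, 19, 18)),
    fake_run(c("E", "B", "A"), c(20, 19, 18))
  )
  agg <- aggregate_runs(runs)
  oracle <- oracle_aggregate(runs)
  expect_equal(agg$antigen_id, oracle$antigen_id)
  expect_equal(agg$inclusion_proportion, oracle$inclusion_proportion)
  expect_equal(agg$average_rank_score, oracle$average_rank_score)
  expect_equal(agg$weighted_mean_rank, oracle$weighted_mean_rank)

  ## spot values: B appears 3/3 with mean rank (19+20+19)/3
  b <- agg[agg$antigen_id == "B", ]
  expect_equal(b$inclusion_proportion, 1)
  expect_equal(b$average_rank_score, 58 / 3)

  ## order invariance
  agg_perm <- aggregate_runs(runs[c(3, 1, 2)])
  expect_equal(agg, agg_perm, ignore_attr = TRUE)
})

test_that("weighted mean rank has the documented arithmetic and bounds", {
  runs <- c(
    replicate(5, fake_run("X", 10), simplify = FALSE),
    replicate(5, fake_run("Y", 20), simplify = FALSE)
  )
  agg <- aggregate_runs(runs)
  ## X in 5/10 runs at rank 10 -> WMR 5; Y in 5/10 at 20 -> WMR 10
  expect_equal(agg$weighted_mean_rank[agg$antigen_id == "X"], 5)
  expect_equal(agg$weighted_mean_rank[agg$antigen_id == "Y"], 10)

  always_top <- replicate(4, fake_run("Z", 20), simplify = FALSE)
  expect_equal(aggregate_runs(always_top)$weighted_mean_rank, 20)
})

test_that("stage-2 selection takes the union (or top-m) of top lists", {
  same <- replicate(3, fake_run(sprintf("G%02d", 1:20), 20:1),
                    simplify = FALSE)
  expect_length(select_stage2_features(aggregate_runs(same)), 20L)
  disjoint <- list(fake_run(sprintf("A%02d", 1:20), 20:1),
                   fake_run(sprintf("B%02d", 1:20), 20:1))
  expect_length(select_stage2_features(aggregate_runs(disjoint)), 40L)
  agg <- aggregate_runs(disjoint)
  expect_length(select_stage2_features(agg, rule = "top_m", m = 7), 7L)
})

test_that("the tree stage solves a perfectly separable problem at depth 1", {
  set.seed(5)
  n <- 60
  labels <- rep(c("patient", "control"), each = n / 2)
  m <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("G%02d", 1:4)))
  m[, "G02"] <- ifelse(labels == "patient", 10, 0)
  pm <- fit_panel_tree(m, labels, seed = 1)
  expect_identical(pm$panel, "G02")
  tree_m <- pm$metrics[pm$metrics$rule == "tree", ]
  expect_equal(tree_m$sensitivity, 1)
  expect_equal(tree_m$specificity, 1)

  const <- matrix(1, n, 3, dimnames = list(rownames(m), paste0("C", 1:3)))
  expect_error(fit_panel_tree(const, labels), "no split")
})

test_that("the panel never exceeds the cap", {
  nc <- normalized_cohort(recovery_sim(seed = 19))
  calls <- dichotomize(nc$x, compute_cutoffs(nc$x))
  bs <- biomarker_scores(calls)
  cand <- select_candidates(bs)
  for (cap in c(3L, 10L)) {
    pm <- fit_panel_tree(nc$x$intensity[, cand, drop = FALSE], nc$x$cohort,
                         max_panel_size = cap, seed = 2, calls = calls)
    expect_lte(length(pm$panel), cap)
  }
})

test_that("any-positive classification matches hand counts", {
  pos <- matrix(FALSE, 6, 3,
                dimnames = list(sprintf("S%d", 1:6), c("G1", "G2", "G3")))
  pos["S1", "G1"] <- TRUE            # patient, 1 marker positive
  pos["S2", c("G1", "G3")] <- TRUE   # patient, 2 positive
  pos["S5", "G2"] <- TRUE            # control false positive
  labels <- c("patient", "patient", "patient", "control", "control",
              "control")
  calls <- structure(list(positive = pos, sc_ratio = pos * NA,
                          cutoffs = NULL,
                          cohort = stats::setNames(labels, rownames(pos))),
                     class = "sero_calls")
  ap <- any_positive_classify(calls, c("G1", "G2", "G3"))
  expect_equal(ap$predicted,
               c("patient", "patient", "control", "control", "patient",
                 "control"))
  expect_equal(ap$n_positive, c(1, 2, 0, 0, 1, 0))
  ## hand-counted: sens 2/3, spec 2/3
  oracle <- oracle_any_positive_metrics(pos, c("G1", "G2", "G3"), labels)
  expect_equal(unname(oracle["sensitivity"]), 2 / 3)
  expect_equal(unname(oracle["specificity"]), 2 / 3)

  expect_error(any_positive_classify(calls, character(0)), "empty")
  expect_error(any_positive_classify(calls, "G9"), "G9")
})

test_that("cumulative panel metrics are monotone and consistent", {
  for (s in 1:30) {
    fx <- random_calls(n = 16, p = 6, seed = 700 + s)
    panel <- sample(colnames(fx$calls$positive), 4)
    cum <- cumulative_panel_metrics(fx$calls, fx$labels, panel)
    expect_true(all(diff(cum$sensitivity) >= 0))
    expect_true(all(diff(cum$specificity) <= 0))
    ## final row equals the full-panel any-positive metrics
    oracle <- oracle_any_positive_metrics(fx$calls$positive, panel,
                                          fx$labels)
    expect_equal(cum$sensitivity[4], unname(oracle["sensitivity"]))
    expect_equal(cum$specificity[4], unname(oracle["specificity"]))
  }
})

test_that("a marker positive in no sample leaves cumulative metrics
           unchanged", {
  fx <- random_calls(n = 12, p = 4, seed = 808)
  fx$calls$positive[, 2] <- FALSE
  panel <- colnames(fx$calls$positive)[1:3]
  cum <- cumulative_panel_metrics(fx$calls, fx$labels, panel)
  expect_equal(cum$sensitivity[2], cum$sensitivity[1])
  expect_equal(cum$specificity[2], cum$specificity[1])
})

test_that("the forest ensemble is reproducible from its master seed", {
  fx <- random_calls(n = 24, p = 8, seed = 101)
  e1 <- run_forest_ensemble(fx$intensity, fx$labels, n_runs = 5,
                            n_trees = 30, seed = 11)
  e2 <- run_forest_ensemble(fx$intensity, fx$labels, n_runs = 5,
                            n_trees = 30, seed = 11)
  expect_identical(lapply(e1, `[[`, "importance"),
                   lapply(e2, `[[`, "importance"))
  ## run seeds follow the documented counter scheme
  expect_equal(vapply(e1, `[[`, numeric(1), "seed"), 11 + 1:5)
})
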