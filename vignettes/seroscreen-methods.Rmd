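---
title: "Methods: seroreactivity scoring and autoantibody panel discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seroreactivity scoring and autoantibody panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
measurement model, the scoring and panel-selection procedure, every
numerically consequential convention, and the design decisions that were
genuinely open — together with what the synthetic-data validation does and
does not demonstrate about real serology data.

## 1. The measurement and its pre-processing

A serology protein microarray reports, for one serum sample, a relative
fluorescence unit (rfu) per spot; each antigen is printed in quadruplicate
and a local background estimate accompanies every spot. The package's
analysis object is built in a fixed order:

1. **Background subtraction**: `rfu - background_rfu`, floored at 0.
   Negative fluorescence is non-physical, and an all-negative antigen
   would break the strictly-positive-median precondition of intra-array
   normalisation. The floor is a convention, not a claim about noise.
2. **Replicate collapse**: the median of the replicate spots (for
   quadruplicates, the mean of the two central readings — the package's
   even-count median convention throughout).
3. **Array QC**: each array is rank-correlated with the run's reference
   serum; `rho < 0.5` fails, as does a median replicate coefficient of
   variation above 0.5. The 0.5 correlation threshold is the field's
   cross-site concordance criterion reused as an array-level criterion;
   the CV bound is a package default, since no numeric replicate-QC rule
   is standard. Exclusion happens **before** normalisation (whether QC
   preceded or followed normalisation is not standardised; excluding
   first keeps corrupted arrays out of the quantile pool) and the counts
   are recorded in the run manifest.
4. **Intra-array normalisation**: every value on an array is divided by
   the array's overall median across antigens, excluding control spots
   (identified by a reserved antigen-id prefix, default `CTRL`). The
   post-condition — every row median exactly 1 — is asserted in tests to
   `1e-12`.
5. **Quantile normalisation** across arrays (tie values receive the
   average of the tied quantile means). The operation is idempotent and
   preserves within-sample ranks; swapping steps 4 and 5 changes the
   result, so the applied order is recorded in the object.

## 2. Seroreactivity: cutoffs, S/C ratios, biomarker scores

For each antigen, over a *basis* sample set, the positivity cutoff is

> cutoff = Q75 + 2.5 × IQR

with quartiles computed by linear interpolation between order statistics
(R's type-7 convention). The convention matters — cutoffs on small cohorts
shift visibly between quantile types — so it is recorded in the cutoff
table's metadata. A value is positive only if **strictly** above the
cutoff, which makes a constant antigen (IQR 0) all-negative rather than
arbitrarily split. For positive calls the signal-to-cutoff ratio
`S/C = intensity / cutoff` (> 1 by construction) measures the magnitude
of seroreactivity.

Per cohort, an antigen's **biomarker score** is
`N_pos × (mean S/C)^(1/3)`: frequency times a tamed magnitude (the cube
root keeps one extreme responder from dominating). Antigens are ranked by
`score_diff = score_patient − score_control`, and `score_diff > 5`
(strict) defines the candidate list.

Open points decided here:

* **Cutoff basis**: whether Q75/IQR should be computed over all discovery
  sera or controls only is genuinely ambiguous in practice. Both are
  first-class (`basis = "all"` is the default; `"controls"` is one
  argument away) and every output records which was used. With moderate
  positivity rates the difference is small because positives sit far
  above Q75.
* **What the >5 rule applies to**: the package applies it to the
  patient − control difference, not the raw patient score, because the
  ranking that precedes the rule is defined on the difference.
* **Degenerate cutoffs**: an antigen that is identically 0 after the
  background floor has cutoff 0; a positive call at "above 0" would be
  meaningless, so such antigens are declared unscorable, dropped from the
  calls, and counted in a warning.
* **Validation cohorts**: cutoffs are recomputed within each cohort by
  default (mirroring how an independent cohort is scored on its own
  distribution); passing the discovery `cutoff_table` to `dichotomize()`
  or `serum_scores()` instead freezes the discovery cutoffs.

The per-sample **serum score** is the sum of normalised intensities (the
full intensity, not the excess) over a stated antigen subset at antigens
where the sample is positive; it is additive over disjoint subsets and 0
for a sample with no positive calls. **Breadth** summaries count positive
antigens per sample per cohort.

## 3. Two-stage panel selection

Individually, candidate autoantibodies have single-marker sensitivities of
only a few percent, so the diagnostic signal lives in combinations.
Fitting a single tree to >100 candidates at n ≈ 200 invites overfitting;
the two-stage design first shrinks the feature list by a stability
criterion, then fits one small tree.

**Stage 1 — repeated random forests.** A forest is fitted to the 0/1
cohort outcome on the candidate intensities; the run's top 20 antigens by
importance receive rank scores 20 (best) … 1. This is repeated `n_runs`
times (protocol default 1000; run seeds are `master + 1, master + 2, …`
so the ensemble is reproducible and any single run re-runnable). For each
antigen ever appearing in a top-20 list, the **weighted mean rank** is

> WMR = inclusion proportion × average rank score ∈ (0, 20],

and stage 2 uses the full union of the top-20 lists (a `top_m`-by-WMR
rule is available). Decisions:

* The forests are **regression forests on the numeric 0/1 outcome with
  permutation importance** — matching the protocol's "random forest
  regression" wording for a binary outcome — with a classification-forest
  (Gini importance) mode behind a flag.
* Features are the **continuous normalised intensities**, not the binary
  calls: tree split thresholds are naturally continuous, and the binary
  representation discards the S/C magnitude.
* Unstated hyperparameters default to `n_trees = 500`,
  `mtry = floor(sqrt(p))`, full bootstrap; all recorded in the manifest.
* With fewer than 20 features the "20 = best" anchor is kept (scores
  20 … 21 − p); importance ties break by stable antigen order.

**Stage 2 — classification tree.** A binary CART (Gini impurity) is grown
on the union features (`minsplit = 10`, growth `cp = 0.002`, 10-fold CV)
and pruned by cost-complexity until its distinct split antigens fit the
panel cap (default 10). The **panel** is those antigens in first-use
(pre-order) order.

The pruning rule was the least determined design point. The conventional
cross-validated 1-SE rule turned out, on cohorts of this size with
per-marker sensitivities of 3–18%, to plateau at 4–6 splits: each
additional marker adds little CV accuracy even when it is a true
biomarker, because each contributes only ~15% sensitivity. The resulting
4-marker panels under-use the panel budget and fall far short of a
ground-truth panel under the any-positive rule. Since the discovery
protocol this package follows evidently reports a full-size (10-marker)
tree with apparent (resubstitution) performance, the default
`prune_rule = "cap"` prunes only to the cap; `"1se"` (falling back to the
minimum-CV-error tree if 1-SE selects the stump) and `"min"` remain
available for users who want conservative trees. Apparent tree metrics
should be read as resubstitution estimates; honest performance estimates
come from an independent cohort, as in `scripts/acceptance.R`.

**Decision rules.** The tree rule classifies by leaf majority with leaf
probabilities as ROC scores. The **any-positive rule** calls a sample a
patient if it is seroreactive for ≥ 1 panel antigen; its ROC score is the
count of positive panel antigens. Both are always reported, along with
cumulative sensitivity (non-decreasing) and specificity (non-increasing)
as markers are added in panel order.

## 4. Evaluation

`roc_auc()` sweeps thresholds over unique scores; its trapezoidal AUC is
exactly the Mann–Whitney concordance probability with ties counted ½
(asserted against an exhaustive pairwise oracle in tests). Group
comparisons use the Mann–Whitney U test (exact enumeration when combined
n ≤ 20 without ties, otherwise normal approximation with tie and
continuity correction — the variant is recorded per result),
Kruskal–Wallis, Spearman correlation, and per-group Shapiro–Wilk
normality screening that is reported but never gates anything. All tests
are two-sided at α = 0.05, with no multiple-testing adjustment by default
(Benjamini–Hochberg is available via `p.adjust` on the returned
p-values). Cross-site concordance is per-specimen Spearman ρ with a 0.5
pass threshold.

## 5. The synthetic cohort generator

The generator exists so that every stage can be validated against known
truth; its defaults are the package's statement of a realistic serology
screen.

Log-scale multiplicative model per spot:

> log rfu = log(baseline_antigen) + array_scale + sample_noise
>           [+ spike if truly positive] + replicate_noise,
> spot background added and recorded separately.

| parameter | default | rationale |
|---|---|---|
| antigen baseline | Lognormal(meanlog 7, sd 1.2) | antigen baselines span orders of magnitude; drives the reference-serum rank correlation of clean arrays |
| sample noise sd (log) | 0.8 | yields a per-antigen null positivity of ≈ 3% under the IQR cutoff, i.e. single-marker specificities ≈ 95–97%, matching the 86.7–100% range reported for such screens, and keeps serum scores continuous enough for rank tests |
| spike factor | Lognormal(meanlog log 20, sd 0.6) | a true seroreactive signal should sit well above the cutoff (call probability ≈ 0.94, typical S/C ≈ 2–6) |
| array scale sd (log) | 0.2 | makes intra-array normalisation non-trivial |
| replicate noise sd (log) | 0.1 | quadruplicate CV ≈ 10%, well under the QC bound |
| spot background | Lognormal(log 100, 0.3) | right-skewed local background, subtracted exactly on clean data |
| spike probabilities | 0.15 patients / 0.02 controls on planted antigens | single-marker sensitivities in the low-tens of percent at high specificity, the regime such screens report |

Positivity is a latent Bernoulli per (sample, planted antigen) expressed
as a multiplicative spike — mirroring the positive/negative semantics the
scoring uses downstream. QC failures replace an array's intensities with
uncorrelated lognormal noise. The reference serum is drawn from the
background model with the same antigen baselines, so its rank correlation
with clean arrays sits comfortably above the 0.5 QC threshold while
corrupted arrays fall to ρ ≈ 0.
`generate_cohort(config, cohort_seed =)` yields independent cohorts on
the same array platform (same baselines, same planted antigens) for
discovery/validation designs.

**What this does not emulate**: spatial artefacts and spot morphology,
scanner saturation, batch structure beyond a per-array scale factor,
plasma-versus-serum differences, antigen–antigen correlation (antibody
cross-reactivity), and any dependence between a sample's planted
positives. Passing recovery tests on this generator demonstrates that the
pipeline's statistics do what they claim under a clean null and a planted
alternative — not that the pipeline is robust to every failure mode of
real arrays.

## 6. Validation problem sizes

The package's own validation (test suite and `scripts/acceptance.R`) uses:
a full-size 1627-antigen × 209-sample matrix for the normalisation
contracts; 200 antigens / 15 planted / 100 + 100 samples over 20 seeds for
candidate recovery (median planted recovery and score-diff ranking AUC)
and for end-to-end panel recovery against a ground-truth oracle panel on
an independently simulated validation cohort, with the forest stage scaled
to 100 runs × 100 trees; and 400 null replicates (100 antigens, 30 + 30)
for the serum-score rank-sum type-I error check. These sizes are the
package's chosen validation design: large enough for stable medians,
small enough to run routinely.

## 7. Known limitations

* Tree-rule metrics on the discovery cohort are resubstitution estimates;
  the package deliberately reports them alongside independent-cohort
  evaluation rather than nested cross-validation (not part of the
  protocol it implements).
* No confidence intervals on AUC; no survival or longitudinal analysis.
* The candidate filter applies no multiple-testing correction across
  antigens (by protocol); the score_diff > 5 rule is a heuristic whose
  false-discovery behaviour depends on cohort size.
* Quantile normalisation assumes most antigens are non-differential
  between cohorts; with a large planted fraction it would shrink true
  signal.
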