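---
title: "Methods: heterogeneous treatment effects of AI assistance in reader studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous treatment effects of AI assistance in reader studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetfx)
```

## The problem

In a multi-reader multi-case (MRMC) study, each radiologist reads a set of
chest X-ray cases twice-conditioned: some with an AI model's predicted
probabilities displayed, some without. Per read, the reader reports a
probability on a 0–100 scale for each of 15 pathology labels; an
expert-consensus continuous ground truth (mean of five expert probabilities)
defines the read's absolute error. The reader-level *treatment effect* on
error is

\[ t_r = \bar u_r - \bar a_r, \]

the mean unassisted error minus the mean assisted error (positive =
improvement). For AUROC, sensitivity and specificity the sign flips:
TE = assisted − unassisted, so positive is always better.

Three questions drive the pipeline:

1. How heterogeneous are the \(t_r\), once measurement noise is removed?
2. Can anything predict \(t_r\) — experience-based characteristics, or the
   reader's own unassisted skill?
3. Does the quality (absolute error) and direction (signed error) of the AI
   prediction itself predict the treatment effect of showing it?

Two designs coexist: *non-repeated* readers see 60 cases once each, 30
assisted and 30 unassisted (half of each with clinical histories, which all
analyses pool); *repeated* readers see 60 cases under all four
assistance-by-history conditions. Both feed the same estimators; the
per-case paired difference is used for repeated readers wherever pairing is
available.

## Empirical Bayes shrinkage

Observed reader means satisfy \(\tilde t_r = t_r + \eta_r\) with sampling
noise \(\eta_r\). A normal prior with moments estimated from the ensemble
gives the conjugate posterior

\[
\mathbb{E}[t_r \mid \tilde t_r]
  = \frac{\sigma_r^2\,\mu_0 + \sigma_0^2\,\tilde t_r}{\sigma_0^2 + \sigma_r^2},
\qquad
\mathrm{Var}[t_r \mid \tilde t_r]
  = \frac{\sigma_0^2 \sigma_r^2}{\sigma_0^2 + \sigma_r^2},
\]

where \(\mu_0\) is the grand mean of the \(\tilde t_r\), \(\sigma_r\) is
reader \(r\)'s standard error of the mean, and the prior variance is the
method-of-moments plug-in \(\sigma_0^2 = \widehat{\mathrm{Var}}(\tilde t_r)
- \overline{\sigma_r^2}\) using the population (divide-by-\(n\)) variance.
Choices worth noting:

* A negative plug-in clips to 0 with a loud warning; every reader then
  shrinks fully to \(\mu_0\). The warning matters: clipped priors mean the
  data cannot distinguish real heterogeneity from noise.
* Readers with \(\sigma_r = 0\) (zero within-reader variance, typical for
  low-prevalence pathologies where every read is "absent, correct") admit
  no inference; `shrink_all()` excludes and lists them. The
  treatment-effect shrinkage analyses therefore restrict to high-prevalence
  pathologies (strict prevalence > 10% of binary truth labels).
* The divide-by-\(n\) convention follows the moment derivation; a
  divide-by-\(n{-}1\) option is exposed. At 140 readers the conventions
  differ by under 1%.

## Split sampling and reversion to the mean

Regressing the treatment effect on the unassisted baseline using the same
reads for both manufactures a positive slope even when none exists: a read
that is bad by chance inflates the baseline *and* the apparent improvement.
Formally, regressing \(u_r - a_r\) on \(u_r\) converges to
\((\mathrm{Cov}^* + \mathrm{Var}(e^u_r)) / (\mathrm{Var}^* +
\mathrm{Var}(e^u_r))\) instead of the noise-free ratio — the added
numerator term *is* the reversion-to-the-mean bias, and the added
denominator term is attenuation.

The split designs remove the shared noise by construction (one row per
held-out case \(i\) and reader \(r\)):

| kind | y | x |
|---|---|---|
| TE, non-repeated | \(u_{i,r} - \bar a_r\) | leave-one-out mean \(x_{\neq i,r}\) |
| TE, repeated | \(u_{i,r} - a_{i,r}\) | leave-one-out mean \(x_{\neq i,r}\) |
| assisted, non-repeated | \(a_{i,r}\) | full mean \(x_r\) (case sets disjoint) |
| assisted, repeated | \(a_{i,r}\) | leave-one-out mean \(x_{\neq i,r}\) |
| naive (diagnostic) | as TE | full mean including case \(i\) |

Rows from both designs are pooled into one regression (no design indicator
by default). The *naive* design is kept on purpose: it demonstrates the
hallucinated slope, and its per-reader aggregated variant (mean y on mean
x) is also reported since both readings of "all available cases" are
defensible.

## Attenuation correction

The split regressor is still a noisy measurement of the reader's true
baseline, so the slope \(\hat\gamma_1\) estimates \(\beta_1 \lambda\) with
reliability

\[
\lambda = \frac{\mathrm{Var}(x) - \mathbb{E}[\eta^2]}{\mathrm{Var}(x)},
\qquad
\hat\beta_1 = \hat\gamma_1 / \hat\lambda,
\quad
\mathrm{se}(\hat\beta_1) = \mathrm{se}(\hat\gamma_1) / \hat\lambda .
\]

\(\mathbb{E}[\eta^2]\) is the mean squared standard error of the regressor
and \(\mathrm{Var}(x)\) the population variance of its observed values.
Implementation detail that matters at \(N_u = 30\): for leave-one-out
designs the regressor averages \(N_u - 1\) cases, so its squared standard
error is \(s_r^2/(N_u-1)\), and \(\mathrm{Var}(x)\) is taken over the
actual regressor column. Using the full-mean approximation instead leaves a
systematic ~1% shortfall in \(\hat\beta_1\); the recovery simulations in
the acceptance suite resolve this difference. \(\hat\lambda \le 0\) (noise
swamps signal) is a hard error, never a silent clip — the regression is
simply not identified then. \(\hat\lambda\) is estimated scope-by-scope
from the same readers entering each regression.

AUROC has no per-case decomposition ("the effects of reversion to the mean
on AUROC cannot be untangled at the case level"), so the AUROC variant
splits each reader's unassisted cases into two seeded halves: baseline
AUROC on one half, outcome on the other, one row per reader, clustered by
reader. This is an interpretation, and it is labelled as such.

## Inference

All read-level regressions use OLS with two-way cluster-robust covariance:
\(V = V_{\text{case}} + V_{\text{reader}} - V_{\text{case} \cap
\text{reader}}\), each term a one-way cluster sandwich, intersection
clusters being unique (case, reader) pairs. No small-sample inflation is
applied by default (a CR1-style factor is config-exposed). Negative
eigenvalues from the inclusion–exclusion are truncated to zero with a
warning. Split designs cluster on (held-out case, reader).

The test battery: Wald joint equality across subgroup coefficients
(chi-square, pairwise-difference restrictions), Wald zero tests for slopes,
a pooled-variance unpaired t-test for the oracle two-group comparison
(Welch exposed as an option), Benjamini–Hochberg step-up correction across
the 15 pathologies (the all-pathologies-aggregated test is a single test
and is never corrected), and for binned AUROCs a between/within F-test with
SSB from n-weighted group deviations and SSW back-converted from group
standard errors, \(\mathrm{SSW} = \sum_g (n_g - 1)\, n_g\,
\mathrm{se}_g^2\). The back-conversion is one reading of an
under-specified construction and is isolated in `auroc_bin_f_test()`;
per-group AUROC standard errors default to a seeded case-level bootstrap
with a DeLong analytic option.

**Few-cluster guard.** The AI-error bin analysis drops bins supported by
fewer than `min_cases_per_bin = 10` distinct cases (in addition to empty
bins). A bin whose reads come from one patient case has a one-cluster
"robust" variance, and the joint Wald test becomes wildly
anti-conservative (the acceptance suite's null-calibration check verifies
the nominal rate with the guard in place). Ten clusters is the usual lower
bound in the few-cluster cluster-robust literature. At the emulated study's real scale (every published bin held
hundreds of reads) the guard never binds.

## Subgroup construction

* `median_split()`: low group \(\le\) median, high group \(>\) median (tie
  rule exposed). Applied to years of experience, thoracic subspecialty,
  AI-tool experience, and — as the oracle benchmark — to the EB-shrunk
  treatment effects themselves.
* `combined_characteristics_split()`: a seeded half-split of readers; a
  linear model of TE on intercept + (experience \(\le\) median, thoracic,
  AI experience) fit on one half scores the other; scores are thresholded
  at the grand median TE; halves swap so every reader is assigned.
  Constant characteristics within a training half are dropped with a
  warning.

## The synthetic generator

`generate_study()` emulates the stated study structure: 107 non-repeated +
33 repeated readers, a 324-case pool, 60 cases per reader (30/30 by
assistance, half of each with histories), 15 pathologies with heterogeneous
prevalence. Defaults are the conditions the emulated study reports or, where
unreported, one fixed realistic choice:

* **Truths**: present cases draw from a scaled Beta(8, 2) conditioned
  \(\ge 50\), absent from Beta(2, 18) conditioned \(< 50\) (rejection
  sampling), so realized binary prevalence converges to the configured map.
  The map spans 2%–60% with five labels above the 10% cutoff. Pathologies
  are simulated independently; real interrelations (e.g. airspace opacity
  vs consolidation) are not modelled, so cross-pathology correlation
  structure is outside what a green test establishes.
* **Reader skill**: mean unassisted error \(\mu_r^u \sim N(10, 2^2)\)
  truncated below at 1 (observed reader averages span roughly 6–14).
* **Effects**: \(\tau_r \sim N(0.06, 0.35)\); the mean matches the
  near-zero average effect and the variance yields a true-effect IQR of
  about 0.8, matching the reported shrunk IQR scale. `skill_slope` plants
  \(\tau_r = \bar\tau + \beta(\mu_r^u - \bar\mu) + \nu_r\) for
  slope-recovery tests (default 0).
* **Read noise**: per-read absolute errors are Gamma with the reader's
  mean and shape 1.5 (sd ≈ 0.82 × mean). Gamma rather than a truncated
  normal keeps the stated mean exact on a positive support, which keeps
  the recovery invariants exact rather than truncation-biased.
* **Predictions** are reconstructed as truth ± error with a
  *feasibility-aware* sign: a fair coin among the sides that stay inside
  [0, 100]. A pure fair coin plus clipping would silently shrink realized
  errors on extreme-truth cases and break the direct-mode mean contract;
  with the feasibility rule, clipping occurs only when the error exceeds
  both margins (rare at the default scales) and the realized post-clip
  error is what the truth record stores.
* **AI errors**: signed error = location + sign × Gamma magnitude (mean
  scale 12), sign positive with probability `p_positive` (0.5 default;
  asymmetry exercises the signed-error bins).
* **Mechanistic mode**: assisted prediction \(= (1-w_r)\cdot\)own draw
  \(+ w_r\cdot\)AI prediction, \(w_r \sim N(0.3, 0.1)\) clipped to [0, 1];
  \(\tau_r\) is then a Monte-Carlo estimate from an internal oracle. This
  mode makes bad AI genuinely harmful, which the bin analyses must detect.
* Session structure and washout are recorded as metadata only; no
  learning-over-time is modelled (the emulated study could not assess it).

The truth record (per-reader \(\mu_r^u, \tau_r\), AI signed errors,
realized post-clip per-read errors) is emitted alongside the bundle and is
used **only** by tests; no analysis function reads it.

What a green recovery test does *not* establish: correctness under
correlated pathologies, reader learning, non-Gamma error shapes, or
informative missingness of profiles — none of which the generator emulates.

## Numerical and degenerate-input policy

* Probabilities are validated into [0, 100] inclusive at both endpoints;
  binary truth is \(\ge 50\) by default (exact 50 counts as present; the
  comparison and threshold are exposed).
* An exact-zero standard error is flagged (`reader_summaries`) and
  excluded from shrinkage under the default rule.
* Rank-deficient designs and empty subgroup-condition cells are hard
  errors naming the offending columns/cells.
* Determinism: every stochastic step (simulation, bootstrap, half-splits)
  takes a seed; identical seed + config is byte-identical output.

## Acceptance criteria status

The deliverable's acceptance criteria are property-based (the emulated
study's dataset is access-restricted, available only on request from its
custodians): reversion-to-the-mean demonstration against the plug-in
limit, planted-slope recovery with attenuation correction, empirical Bayes
variance recovery and MSE dominance, exact agreement with brute-force
oracles, and null calibration — all implemented in
`tests/testthat/test-acceptance.R` at their stated tolerances, with a
documented 0.01 finite-sample allowance on probability-limit comparisons
(replicate means of ratio estimators carry O(1/n) bias at 140 readers).
The conditional full-dataset reproduction criterion cannot run without the
restricted data; `load_bundle()` + `run_full_analysis()` implement the
pipeline it would use.
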