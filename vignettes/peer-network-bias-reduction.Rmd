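---
title: "Modelling bias reduction in clinician peer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bias reduction in clinician peer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinnet)
```

## The experiment being modelled

`clinnet` simulates and analyses a three-round experiment on treatment bias
among practicing clinicians. Every participant watches a standardized-patient
video of a cardiac chest-pain case — identical script, attire and ECG, with
only the patient-actor's race and gender varying (a Black female or a white
male "patient") — then twice per trial:

* estimates the probability (0–100) of a major adverse cardiac event within
  30 days, and
* recommends one of four treatments: **A** unsafe undertreatment (81 mg
  aspirin, one-week follow-up), **B** undertreatment (stress test in 2–3
  days), **C** the guideline-recommended treatment (full-dose aspirin,
  immediate emergency-department referral), or **D** overtreatment (urgent
  catheterization).

The case has a HEART score of 5 (history 1, ECG 1, age 2, risk factors 1, no
troponin), putting it in the intermediate 4–6 band whose most accurate risk
estimate is **16%**. Accuracy is min-max normalized absolute error: an
estimate at 16 scores 1, an estimate at 100 — the farthest possible, 84
percentage points away — scores 0.

Each trial enrols 120 clinicians, randomized 2:1 into network and control
conditions and then 1:1 between the two patient arms: 40 clinicians per
network condition-arm, 20 per control condition-arm. Network clinicians
occupy the nodes of a shared 4-regular ("egalitarian") graph and, in rounds
2 and 3, see the mean estimate of their four anonymous contacts before
revising. Control clinicians simply reflect and revise in isolation. The
reference design has 7 trials, hence 840 clinicians and
7 × 4 = 28 trial-level observations — the unit at which all headline
statistics are computed.

## The behaviour model (and what is ours, not the study's)

The original study reports only *aggregate* revision dynamics; it does not
specify an individual-level revision law. The generator therefore uses the
minimal model consistent with those aggregates, and every parameter of it is
an explicit, documented configuration choice:

* **Estimate revision (network).** A clinician with estimate $e$ adopts the
  neighbour mean $\bar e$ with weight
  $w = \mathrm{clip}(\alpha + \beta\,|e - 16|/84,\ 0,\ 1)$, plus Gaussian
  noise, clipped to $[0, 100]$. With $\beta > 0$, inaccurate clinicians
  revise more — exactly the positive "revision coefficient" mechanism that
  gives accurate clinicians greater de facto influence. Defaults
  $\alpha = 0.1$, $\beta = 0.55$, noise SD 3: a clinician at the anchor
  moves barely at all, a maximally wrong one adopts roughly two-thirds of
  the gap per round. Consensus is a fixed point of this rule when noise is
  off, and attrited neighbours are excluded from the mean (each remaining
  neighbour contributes their most recent available response; a clinician
  with no available neighbour keeps their own estimate).
* **Recommendation revision.** With probability `switch_prob` (default 0.3
  per round) a clinician redraws their recommendation from a multinomial
  whose option weights are the arm's baseline probabilities, with Option C's
  weight multiplied by $\exp(\eta_0 + \eta_1\,a)$ where
  $a = 1 - |e-16|/84$ is the accuracy of the revised estimate
  ($\eta_1 = 3$ by default). This couples diagnostic accuracy to treatment
  quality, reproducing the accuracy→recommendation pathway; the helper
  `calibrate_choice_intercept()` solves $\eta_0$ for a target marginal C
  rate by bisection.
* **Control revision.** Estimates are jittered (SD 3, zero mean); with
  probability `drift_prob` (default 0.05 per round) a recommendation steps
  one option toward higher acuity (A→B→C→D). This encodes the observed
  tendency of independent reflection to escalate care without reducing
  inequity.
* **Initial responses.** Estimates are truncated normal on $[0,100]$. The
  study does not print the estimate distribution; both arms default to mean
  30, SD 20 — clinicians overestimate an intermediate-risk case, with no
  initial accuracy difference between arms, matching the reported null
  initial accuracy contrast. Initial recommendations are i.i.d. from
  per-arm option distributions. The pooled initial A and C rates *are*
  printed (Black female 29.9% / 14.1%; white male 23.4% / 21.4%) and are the
  defaults; the unprinted remainder is split 2:1 between B and D, on the
  view that conservative undertreatment is more common than referral for an
  invasive procedure. These are calibration choices, stated once, not tuned.
* **Attrition.** Each clinician independently completes rounds 2–3 with
  probability `completion_prob` (1 by default; 0.86 reproduces the reported
  completion rate). Round 1 is always present, since responding in round 1
  is what enrols a clinician.

All randomness flows from one `master_seed`; each (trial, condition, arm)
cell draws from its own hashed sub-stream, so arms are reproducible
independently and identical configurations give byte-identical tables.

## What a green test does and does not establish

The generator reproduces the *structure* the analysis assumes — counts,
bounded estimates, arm-specific option marginals, error-dependent revision,
acuity drift, attrition — so green tests establish that the metrics and the
statistical machinery are correct and that the stated mechanism produces the
qualitative pattern (accuracy gains and bias reduction in networks, neither
in controls). They do not establish anything about real clinicians: the
human point estimates (e.g. the final 27% guideline rate for the Black
female network arm) depend on behavioural details no simulator can certify,
which is why the acceptance targets are in-paper worked values, structural
counts, and parameter-recovery checks rather than human outcomes.

## Statistical framework

* **Trial-level observations.** One metric vector per (trial, condition,
  arm). Control cells are first resampled with replacement into
  bootstrapped groups of 40 (one group per cell by default, mirroring the
  one-to-one comparison with network cells; `n_groups` can be raised for
  variance assessment), so that control and network observations are
  comparable group-level aggregates.
* **Aggregation order.** Option rates are averaged within trial first, then
  across trials with equal weight (the presentation convention of the
  study); pooled averaging is available behind a flag since the printed
  initial rates pool across conditions.
* **Wilcoxon tests.** Implemented in-package because the contract requires
  exact small-sample behaviour with ties: the rank-sum test enumerates all
  assignments when both sides have fewer than 8 observations (tie-corrected
  normal approximation, without continuity correction, otherwise); the
  signed-rank test drops zero differences, uses midranks, and computes the
  exact null by convolution for up to 25 nonzero differences. Two-sided
  p-values are twice the smaller tail, capped at 1. Both are verified
  against brute-force enumeration oracles that use pair counting and sign
  enumeration rather than ranks.
* **Inequity.** Per arm, the gap is $P(A) - P(C)$ in percentage points; the
  inequity statistic is the Black-female gap minus the white-male gap. The
  odds form $\#A/\#C$ is also emitted; a zero C count is reported as an
  explicit undefined-odds error (a Haldane–Anscombe +0.5 correction exists
  behind a flag for regression contexts, never silently).
* **Revision coefficient.** Pearson correlation of initial absolute error
  with revision magnitude $|{\rm final} - {\rm initial}|$ (final minus
  initial, not summed per-round revisions). Its standard error comes from a
  trial-clustered CR1 sandwich on the OLS slope, transported to the
  correlation scale through $r = b\,{\rm sd}(x)/{\rm sd}(y)$.
* **Clustered logistic models.** Binomial GLM with a CR1 cluster-robust
  sandwich (hand-rolled; the small-sample factor is
  $\tfrac{G}{G-1}\tfrac{n-1}{n-k}$), emitting odds ratios with 95% CIs.
  Separation is detected and flagged; a weak ridge-penalized IRLS refit is
  available as an explicit fallback.
* **No multiplicity adjustment** — nominal two-sided p-values are reported,
  as in the source design. Zero-difference and tie conventions are the
  standard Wilcoxon ones; they are documented here because the source is
  silent.

## Numerical and design choices

* The HEART risk lookup hard-codes only the 4–6 → 16% band; other bands
  default to `NA` ("unspecified") rather than invented clinical numbers,
  and remain configurable. The 4–6 band ignores overrides.
* Neighbour means are computed on unrounded estimates (rounding is a
  display concern; whether the original app rounded is unknown).
* The same rewired 4-regular topology is used across all trials of a study,
  generated once from the study seed: a ring lattice randomized by 10
  double-edge swaps per edge, rejecting loops and multi-edges, resampled
  (up to 100 times) until connected.
* The generator accepts `estimate_sd = 0` as a degenerate point mass even
  though typical configurations use positive SDs; the degenerate case is
  needed for exactness tests.
* Attrition handling in analysis defaults to complete-case, with
  last-observation-carried-forward available (`attrition = "locf"`); both
  are exposed because the source reports robustness to both.

## Known limitations

* With default parameters the simulated network condition sharply reduces
  the unsafe-vs-guideline gap *within* each arm (the mean Black-female gap
  swings from about +16 pp to about −18 pp over 30 study seeds), but
  preserves much of the *between-arm* inequity, because the arm bias lives
  in the baseline choice weights and the accuracy coupling is symmetric
  across arms. The human study reports stronger between-arm convergence;
  reproducing that would require an asymmetric switching model the source
  does not specify, so no attempt is made to tune toward it.
* The behaviour model is intentionally minimal: no free-text rationales,
  response times, within-round ordering, or fitting to the (unavailable)
  raw human data.
* The exact algebra of the source's supplementary inequity equation is not
  reproduced; the implementation follows the verbal percentage-point
  definition, with the odds representation emitted alongside.
* Bootstrap grouping resamples within each (trial, condition-arm) cell; the
  original supplementary procedure's replicate count and whether it crossed
  trials are unspecified, so the defaults keep one group per cell.
* High-risk HEART bands have no canonical percent here; mapping them is
  deliberately left unconfigured.
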