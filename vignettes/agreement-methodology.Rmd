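---
title: "Statistical methodology for multi-rater ordinal grading studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methodology for multi-rater ordinal grading studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelkappa)
```

panelkappa implements the statistical machinery of a blinded multi-rater
validation study of ordinal cancer grading: groups of raters (grading
algorithms, general pathologists) each assign an ISUP grade group to a set
of prostate biopsies, their agreement with an expert-panel reference
standard is quantified, and the groups are compared with resampling-based
inference. This vignette describes the model and the procedures, the
parameters that matter, the design choices we made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The grade scale

Every rating is one category of a six-level ordinal scale: 0 denotes a
benign (nontumor) biopsy and k = 1..5 denotes ISUP grade group k. Grade
groups derive from Gleason pattern pairs by the fixed table implemented in
`isup_from_gleason()`: 3+3 → GG1, 3+4 → GG2, 4+3 → GG3, 4+4/3+5/5+3 → GG4,
4+5/5+4/5+5 → GG5. Obsolete patterns 1-2 are rejected rather than clamped,
since modern grading excludes them. Placing benign at 0 on the same axis
as GG1-GG5 makes the quadratic disagreement weights below well defined for
the whole outcome space.

## Agreement: quadratically weighted kappa

The primary endpoint per rater is Cohen's kappa with quadratic weights
against the reference standard. With K = 6 categories and weights
$w_{ij} = (i-j)^2/(K-1)^2$,

$$\kappa = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}},$$

where $O$ is the observed joint proportion matrix of the two rating
vectors and $E$ the outer product of their marginals. Disagreements are
penalized by squared ordinal distance, so calling a GG5 benign costs 25
times as much as calling it GG4.

Two conventions are fixed deliberately:

* **K is always 6**, even when some grades are absent from a sample, so
  weights — and therefore kappas — are comparable across panels and case
  subsets. Whether to use the full or the observed label space is a
  genuine fork in weighted-kappa implementations; we fix the full space
  for cross-panel comparability.
* **Degenerate kappa is `NA`, not 0 or 1.** When both raters are constant
  and identical the expected weighted disagreement is zero and the ratio
  is undefined; `qw_kappa()` returns the `NA` marker and never raises, and
  downstream resampling treats such replicates by its own redraw policy.

Missing reviews are excluded pairwise (complete-case per rater-reference
pair), matching designs in which pathologist panels review only subsets of
the cases.

## Detection metrics and the representative rater

Tumor detection is scored on the binarized scale (cancer = grade ≥ 1):
sensitivity TP/(TP+FN), specificity TN/(TN+FP) and balanced accuracy,
their mean. A group is summarized by its *representative rater* — the
rater at the median balanced accuracy — rather than by averaging rates
across raters. For an even rater count we take the lower of the two middle
values, so the representative is always an actually existing rater, and
ties on the selected value break to the lexicographically smallest rater
id, making selection deterministic.

## Consensus reference standards

Two protocols are implemented, mirroring how expert panels set reference
standards in practice:

* `sequential_majority()`: two uropathologists review each specimen; a
  third reviews only discordant cases, and the strict 2-of-3 majority
  wins. If the adjudicator agrees with neither earlier review, no
  majority exists; we return the ordinal median of the three grades and
  set an `unresolved` flag. The median preserves ordinality and surfaces
  the ambiguity instead of silently privileging one reviewer.
* `panel_majority()`: the modal grade of k ≥ 2 votes. Among tied modes,
  the ordinal median of all votes wins if it is itself a tied mode;
  otherwise the lowest tied mode is chosen — a conservative tie-break that
  mirrors clinical caution against overcalling, and keeps the vote
  deterministic and permutation-invariant.

## Group comparison: permutation test

Groups are compared on the mean of their per-rater kappas,
$T = \bar\kappa_A - \bar\kappa_B$. Under the null that group labels are
exchangeable, `permutation_test()` reassigns labels over the pooled raters
preserving group sizes. The two-sided p-value is the proportion of
reassignments with $|T^*| \ge |T_{obs}|$ — counting the absolute statistic
directly rather than doubling a one-sided tail, which is exact under
exchangeability and cannot exceed 1. When
$\binom{n_A+n_B}{n_A} \le 20{,}000$ the null is enumerated exhaustively
and the p-value is an exact ratio of counts, independent of the seed; the
threshold covers the smaller side of realistic panel sizes at trivial
cost. Larger problems use Monte-Carlo sampling with the add-one
correction $p = (b+1)/(m+1)$, the standard estimate that is never zero.

## Uncertainty: crossed rater-by-case bootstrap

Confidence intervals for a group's mean kappa must propagate two sources
of variability: which raters the group happens to contain, and which cases
the study happens to grade. `bootstrap_ci()` therefore resamples **both**
units: each replicate independently draws raters with replacement and
cases with replacement, and averages the resampled raters' metric against
the reference on the resampled cases. We read "both rater and case as the
resampling unit" as this crossed (not nested) two-way scheme. The
interval is the percentile interval of the replicate distribution with
1,000 replicates by default — the interval type and replicate count are
open choices; percentile is the simplest interval with honest asymmetric
behavior near the kappa ceiling at 1, and BCa's acceleration correction is
poorly defined for the two-way scheme. Replicates with an undefined
metric (degenerate kappa, or a rater left with no reviewed case) are
redrawn up to a cap of 10 × the replicate count and reported in
`n_degenerate`.

The crossed scheme is only approximately calibrated — two-way bootstrap
intervals for reader studies are known to be rough — which is why the
package validates it by *simulation coverage* rather than by nominal
claims: in the bundled validation study (300 simulated panels of 150 cases
and 10 confusion-model raters, 500 replicates each, with the true mean
kappa known exactly from the closed-form oracle), the 95% interval is
required to cover the truth at a rate in [0.85, 0.99].

## Ensembling algorithms

`ensemble_grades()` combines several algorithms' grades per case by the
ordinal median, with even counts resolved to the lower of the two middle
grades. The median is robust to outlier algorithms; rounding toward
benign biases the ensemble toward specificity, the direction in which
combining over-sensitive graders is expected to help.

## The synthetic panel generator

No per-case predictions from a real study are consumed; all validation
runs on simulated panels whose structure matches the analysis
assumptions.

**Case population.** True grades are i.i.d. draws from a six-probability
prevalence. The default, `default_prevalence()` =
(0.29, 0.25, 0.13, 0.11, 0.11, 0.11), is the case mix of a large
multi-site prostate biopsy cohort (29% benign, 25% GG1, then 13/11/11/11%).

**Raters.** Two interchangeable rater models:

* *Confusion-model*: grades drawn from a 6×6 row-stochastic matrix indexed
  by the true grade, independent across cases and raters. Its expected
  kappa against any other confusion-model rater (or the perfect reference,
  `diag(6)`) has the closed form implemented in `expected_qwk()`, which is
  what makes simulation studies with known truth possible.
* *Latent-threshold*: the rater's latent score is
  truth + bias + difficulty + Normal(0, σ), thresholded at the
  half-integers 0.5, ..., 4.5 and clipped to [0, 5]. Half-integer
  thresholds are the simplest ordinal link that keeps the bias
  interpretable in grade units (bias +0.5 pushes half the borderline cases
  up one grade). The per-case difficulty is drawn once per panel from
  Normal(0, τ) and shared by all latent raters, which reproduces the
  "hard case" correlation between raters that makes the case axis of the
  bootstrap meaningful; `latent_confusion()` gives the marginal confusion
  matrix of such a rater analytically (add τ to σ in quadrature).

**Missingness** is applied uniformly at random per rater, matching
subset-review designs; it is not informative.

**The default study shape.** `default_sim_config()` generates the panel
the package analyzes out of the box: 70 cases, 15 algorithm raters
(slight overgrading bias, mean +0.10 grade units, σ centered at 0.93) and
13 general pathologists (undergrading bias, mean −0.15, σ centered at
1.48), with τ = 0.15. The σ centers were set once, analytically, so that
the groups' expected mean kappas against the reference are ≈ 0.88 and
≈ 0.77 — a mean-kappa gap of ≈ 0.11, the size of gap the pipeline is
designed to detect with these group sizes; the small per-rater spreads in
bias and σ create realistic rater heterogeneity. The reference column is
the simulated truth, i.e. the expert-consensus reference is treated as
exact.

**What the generator does not emulate.** Real raters' grade confusion is
concentrated between adjacent *cancer* grades, while benign/cancer
discrimination is far better than a constant-noise ordinal model implies;
the homogeneous latent model therefore produces detection sensitivities
and specificities noticeably lower than real graders have at matched
kappa. It also represents scanner and laboratory domain shift only
implicitly (as group-level confusion differences), and the shared
difficulty τ and noise σ have no calibrated real-data targets — they are
structurally realistic, not fitted. Passing tests on these panels
validate the *statistics* (kappa, tests, intervals, orderings), not any
claim about real raters.

## Numerical and validation choices

* Kappa is computed from tabulated counts on the fixed 36-cell space;
  equality checks against the brute-force double-sum oracle are required
  to 1e-12 over 1,000 random instances.
* Permutation tie handling: permuted statistics are counted as extreme
  when $|T^*| \ge |T_{obs}| - 10^{-12}\max(1, |T_{obs}|)$, so exact ties
  from discrete metrics are never lost to floating-point noise.
* Consensus rules are verified exhaustively against enumerate-and-vote
  oracles over all 6³ reviewer triples and 6⁴ quadruples.
* Simulator fidelity is checked with 50,000 draws per confusion row
  (total-variation distance < 0.01 per row, a band an unbiased sampler
  passes with wide margin while a biased one cannot), and pairwise kappa
  at 50,000 cases against `expected_qwk()` (within 0.01).
* Type-I error of the permutation test is measured over 1,000 null
  studies (two groups of 10 kappas from one distribution, α = 0.05,
  required rejection rate in [0.03, 0.07]); bootstrap coverage over 300
  simulated panels as described above. These problem sizes give the
  checks enough resolution to catch calibration errors of a few
  percentage points while keeping the default validation run short.
* All simulation is reproducible: a panel is a pure function of its
  config (including the seed), and `evaluate_panel_study()` is a pure
  function of (panel, seed), with internal child seeds derived
  deterministically for the bootstrap of each group and each test.

## A worked run

```{r example, eval = FALSE}
panel <- simulate_panel(default_sim_config(seed = 1))
report <- evaluate_panel_study(panel, seed = 17)
glance(report)
autoplot(report)
```

## Known limitations

* The reference standard is treated as error-free truth; reference
  uncertainty (imperfect uropathologists) would attenuate all kappas and
  is not modeled.
* The crossed bootstrap has no finite-sample calibration guarantee; its
  coverage band is validated empirically for the simulated regime only.
* Detection metrics of simulated raters are pessimistic relative to real
  graders at matched kappa (see above).
* Only the explicit two-plus-adjudicator protocol and a generic majority
  vote are implemented; consensus-by-discussion processes cannot be
  computed from vote data.
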