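---
title: "Consensus multiblock OPLS for bioactivity-guided metabolomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus multiblock OPLS: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbopls)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken where
the design was genuinely open.

## The scientific setting

A plant-extract screen couples two untargeted LC-MS feature tables — one per
electrospray ionization mode — with a plate-based α-glucosidase inhibition
assay. The design emulated throughout is 9 trees × 3 organs (leaf, stem
bark, fruit) × 2 collection sites (littoral, mountain) = 54 extracts. The
response is the percent inhibition at a reference extract concentration of
10 µg/mL, computed from 405 nm absorbances as
$(A_{ctrl} - A_{sample})/A_{ctrl} \times 100$. Negative inhibition values
(sample absorbance above the control) are deliberately retained in the
response vector: clipping would discard information the multivariate model
can use, and only the generator clips its *latent* activities to the
physically meaningful [0, 100] range.

## The consensus OPLS model

Orthogonal projections to latent structures (OPLS) splits predictor
variation into one component predictive of the response and components
orthogonal to it. The multiblock ("consensus") variant used here operates on
sample-similarity kernels so that blocks of very different widths can be
combined without one dominating by size:

1. Each block is column-scaled (unit variance by default) and its linear
   kernel $K_b = X_b X_b^\top$ is normalized to unit Frobenius norm.
2. The consensus kernel is $K = \sum_b w_b K_b$ with weights initialized
   uniformly.
3. $(K, y)$ is decomposed by a kernel OPLS: the predictive score is
   $t = K y_c / \sqrt{y_c^\top K y_c}$; each orthogonal component is
   extracted from the part of $K$ not explained by $t$, and $K$ is deflated
   by the corresponding projector. This is algebraically the kernel
   formulation of primal OPLS on the weighted concatenated blocks; the test
   suite verifies the reduction to textbook NIPALS PLS1 when one block and
   zero orthogonal components are requested.
4. Block weights are updated proportional to the squared congruence
   $\left(t^\top K_b t / t^\top t\right)^2$ between each normalized block
   kernel and the predictive-score outer product, renormalized to sum to
   one, and steps 2–4 iterate until the weights move by less than $10^{-6}$
   (at most 100 iterations). This measure is bounded, symmetric, and makes
   duplicated blocks receive exactly equal weights.

The predictive score is **oriented** so that it correlates positively with
the supplied response; "right of the loading plot" therefore always means
"associated with stronger inhibition". If the response is negated the score
mirrors exactly — the orientation follows the response that was fitted, and
the high-inhibition end is recovered by mirroring the coordinates; the test
suite pins this behavior down, together with invariance to sign flips of
the variable axes (kernels are blind to them).

R²Y is computed from the single-component regression of the centered
response on the predictive score. Q² uses stratified k-fold
cross-validation (default 7 folds, stratified by organ × site cell so each
fold sees the full design): every fold refits the complete iterative model —
scaling, kernels, block weights — on the training samples only, projects the
held-out samples through the stored scaling and deflation sequence, and
accumulates PRESS; $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}_{tot}$. The
permutation test re-runs that whole cross-validation under random
permutations of the response, with
$p = (1 + \#\{Q^2_{null} \ge Q^2_{obs}\})/(1 + n_{perm})$.

### Loading coordinates and ion selection

The per-ion "coordinate" on the predictive axis is defined as
$x_j^\top \hat t$ with $\hat t$ the unit-norm predictive score and $x_j$ the
scaled intensity profile — the covariance of the ion with the unit score.
With unit-variance scaling this equals $\sqrt{n-1}\,\mathrm{cor}(x_j, t)$,
so for the 54-sample design the maximum attainable coordinate is
$\sqrt{53} \approx 7.3$ and the historical selection threshold of 5
corresponds to $|r| \approx 0.69$. This is why the threshold is kept at 5 by
default yet documented as scaling-dependent; a percentile alternative
(`threshold_percentile()`, top 2% by default) is available when the scaling
or sample size differs. Selection is one-sided (coordinate strictly greater
than the threshold): the biological question is which ions accompany
*stronger* inhibition. Both ionization-mode blocks share one coordinate
scale, so a single threshold applies to both.

### Numerical choices

* Zero-variance columns are centered but not divided (flagged instead);
  constant ions get correlation 0 during pruning, logged, not an error.
* The orthogonal extraction stops early if the residual orthogonal variance
  falls below $10^{-12}$ (e.g. rank-deficient blocks); the model records the
  number actually extracted.
* Fold assignment is seeded and deterministic; every stochastic step in the
  package derives a stage-specific substream from one master seed, so a
  `(config, seed)` pair reproduces every artifact byte for byte. The run
  manifest stores doubles with 17 significant digits for the same reason.
* `n_ortho` defaults to 1: one predictive + one orthogonal axis is the
  canonical score-plot geometry for this design, where organ structure not
  aligned with inhibition forms a single dominant orthogonal direction.

## Feature filtering

The filter chain is retention-time window → intensity threshold →
correlation pruning, in that order. Decisions taken where the contract left
room:

* "At least one condition" for the intensity rule is read as the three
  *organ* groups, pooling sites, with group **means** compared strictly
  (`> 2000`); organ × site cells and a max statistic are selectable.
* "Same retention time" is quantified as a tolerance of 0.02 min (a typical
  UHPLC alignment width; configurable), with groups closed transitively.
* Correlation is computed on raw peak areas (log and absolute-value options
  exist); the threshold `r ≥ 0.80` is inclusive.
* Within a redundancy cluster the retained representative is the ion with
  the highest median intensity, ties broken by lexicographic ion id — a
  deterministic rule, verified against a brute-force oracle.

The chain is idempotent, and raising the intensity threshold can only
shrink the kept set; both properties are tested.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is validated.

* **Latent activity.** Organ × site cell means default to the emulated
  study's printed values — stem bark 84.7% (littoral) and 69.9% (mountain),
  fruit 13.6% at both sites, leaves 49% at both sites (the only printed
  leaf-level figure; per-site leaf means are a generator choice, not an
  emulation target) — plus tree-level Gaussian noise (sd 6%, in line with
  the reported stem-bark and fruit dispersions), clipped to [0, 100].
* **Feature blocks.** 230 negative-mode and 190 positive-mode ions before
  filtering. Intensities are log-normal — the standard heteroscedastic
  behavior of LC-MS peak areas, which also makes correlation pruning on the
  raw scale non-trivial. Ten active ions (five per block) follow
  $\log I = \text{baseline} + \beta \cdot \text{activity}/100 + \varepsilon$
  with $\beta \approx 2$ (±20% per ion) and residual sd 0.3. Active ions
  elute inside the 0.5–5 min analysis window, as the identifiable bioactive
  constituents of such extracts do. Inactive ions carry random organ
  profiles (sd 0.4) constructed *orthogonal to the organ-mean activity
  pattern*, so "activity-independent" holds by construction rather than
  merely in expectation — these profiles manufacture the orthogonal
  component. Redundant clones duplicate a parent ion at its exact retention
  time (scaled by 0.8 with 3% noise, guaranteeing r > 0.95 and leaving the
  parent the higher-median representative); sub-threshold ions keep every
  organ mean below 2000. With these defaults the post-filter matrix lands
  near the emulated 198 + 160 ions.
* **Assay plates.** The dose response is linear in concentration,
  $f(c) = c/10\,\mu g/mL$ — the simplest monotone shape consistent with a
  single reference dose — so the latent activity is recovered *exactly* at
  the reference dose when the replicate CV is zero (a closure property the
  tests assert). Triplicate wells carry 5% multiplicative noise; six
  enzyme-only control wells are simulated because every inhibition value is
  referenced against their mean, and control error propagates into all
  samples (visible at some seeds as a common few-percent shift of all
  recomputed means). Acarbose is included as a positive control over
  0.2–1 mg/mL, reaching ~99% inhibition at the top dose.

What the generator does **not** emulate: raw spectra, chromatographic peak
shapes, m/z accuracy, isotopes or adducts, between-batch drift, or missing
peaks. Passing tests therefore demonstrate the correctness and calibration
of the *statistical pipeline* under a faithful design geometry — not
robustness to acquisition artifacts that peak-picking software handles
upstream.

## Univariate statistics

Pairwise "post hoc Kruskal–Wallis" comparisons are implemented literally as
two-group Kruskal–Wallis tests (equivalent to rank-sum tests with tie
correction) with Bonferroni multiplication capped at 1; Dunn's many-to-one
test — joint ranks, tie-corrected variance, one-step Bonferroni over the
k − 1 comparisons — is provided separately for comparisons against the
acarbose control. Completely tied data return H = 0, p = 1 rather than the
0/0 indeterminate form. The compact letter display uses insert-and-absorb;
groups are ordered by descending median before lettering, so 'a' labels the
most inhibitory group. Exhaustive comparison against a brute-force minimum
clique cover over all significance patterns on up to five groups shows the
heuristic attains the minimal letter count on every pattern, and the
letter/p-table consistency (share a letter ⇔ not significantly different)
holds by construction.

## Problem sizes used in validation

The shipped validation suite uses the full 54-sample design with the
default 230 + 190 pre-filter ions for recovery claims (20 independent
seeds), 60 + 50-ion signal-free matrices for the null calibration (100
seeds for cross-validated Q², 50 seeds × 19 permutations for the
permutation-p uniformity check), and 1000 null replicates of 6 groups × 9
samples for the family-wise error of the pairwise post-hoc. These sizes
give Monte-Carlo error well inside the asserted margins while keeping the
suite fast on a single CPU.

## Known limitations

* The consensus algorithm extracts a single predictive component (one
  response); multi-response Y and OPLS-DA classification are out of scope.
* IC50 values are reported by assumption-free monotone interpolation by
  default; the four-parameter logistic alternative is provided because the
  underlying assay model is rarely stated in screens of this kind. An IC50
  is undefined (reported as such, not imputed) when the curve never crosses
  50%.
* Correlation pruning keeps exactly one representative per redundancy
  cluster; if two genuinely distinct co-eluting compounds correlate above
  the threshold across all samples, no statistical method of this class can
  separate them.
* The loading-coordinate threshold of 5 is meaningful under unit-variance
  scaling at this sample size; other scalings require the percentile rule.
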