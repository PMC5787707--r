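---
title: "Scoring heterogeneous CRISPR perturbations by within-well classification"
author: "hetscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring heterogeneous CRISPR perturbations by within-well classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetscore)
```

## The problem

Arrayed CRISPR-Cas9 screens read out by high-content imaging face a
compounded heterogeneity problem. Transient transfection reaches only a
fraction of the cells in a well, and among transfected (T(+)) cells only a
fraction — the *penetrance* — is actually edited into a loss-of-function
state. A well is therefore a mixture of wild-type and perturbed cells, and
averaging image features over the well dilutes the phenotype of the edited
subpopulation. On top of that, wells and plates carry technical structure
(staining batches, edge effects, positional gradients) that can be as large
as the biology.

`hetscore` scores such screens at single-cell resolution by exploiting the
mixture itself: the non-transfected (T(-)) cells in every well are an
in-well wild-type reference measured under identical technical conditions.

## The within-well scoring model

For each well the analysis proceeds as follows.

1. **QC.** Wells with fewer than 300 T(+) cells (or fewer than 100 T(-)
   cells) are excluded; a classifier cannot be trained reliably on less.
   The T(+) minimum is the screen's published operating point; the T(-)
   minimum is this package's guard for a stable reference estimate, and
   both are configurable.
2. **Standardization.** Every feature is z-scored by the mean and sample
   SD (n − 1) of the well's own T(-) population. This cancels well-level
   technical offsets exactly to the extent that they act additively on
   both populations.
3. **Dimensionality reduction.** PCA is fitted once on cells pooled across
   all retained wells (defaults: 50 components for cell-morphology feature
   sets, 30 for marker-staining sets). Pooling, rather than per-well fits,
   keeps classifier predicted values comparable across wells; a per-well
   PCA would give every well its own coordinate system.
4. **Bootstrapped penalized classification.** Per well, 100 bootstraps
   each draw 500 T(+) and 500 T(-) cells with replacement (balanced
   regardless of the true T(+)/T(-) ratio), fit an L1-penalized logistic
   regression over a penalty path, and select the penalty by 10-fold
   cross-validated misclassification error with class-stratified folds.
   The CV error at the selected penalty is recorded, and the refitted
   model assigns every cell in the well a predicted value (PV).
5. **Scores.** The *classification score* is
   `0.5 − mean CV misclassification` over bootstraps: 0 when the
   populations are indistinguishable (CV error 0.5), 0.5 at perfect
   separation. The *phenotypic score* is the two-sample
   Kolmogorov–Smirnov statistic between the well's T(+) PV distribution
   and the pooled T(+) PVs of non-targeting control wells.
6. **Hit calling.** A perturbation is a hit when its classification score
   strictly exceeds the Tukey fence Q3 + 1.5 × IQR of the control wells'
   classification scores.
7. **Single-cell gate.** The PV gate is
   `mean + 3 × SD` of the pooled control T(+) PVs (pooled screen-wide,
   matching a single gate value for the screen). T(+) cells strictly above
   it are called phenotypically perturbed and averaged into
   control-referenced perturbation profiles, which feed replicate
   (within-gene) correlation analysis and average-linkage hierarchical
   clustering under correlation distance.

### Choices the method description leaves open

Several details are not pinned down by the published description; the
package adopts the following and treats them as configuration, not facts:

* **PV scale.** The PV is the linear predictor (log-odds of the T(+)
  class), not the fitted probability. The published decision boundary at
  PV = 0 is the natural zero of the logit scale, and averaging over
  bootstraps is done on the logit.
* **Penalty selection.** The penalty minimizing CV misclassification
  error (`lambda.min`), not the 1-SE rule; the recorded misclassification
  is the CV estimate at that penalty.
* **Refit.** After CV, the model refitted on the full bootstrap sample at
  the chosen penalty scores all cells of the well, including cells never
  drawn.
* **Fold assignment** is stratified by class so no CV fold is ever
  single-class.
* **Pooling scope.** PCA and the PV gate are screen-wide; the hit fence
  uses all control wells of the screen.

## The between-well baseline

For comparison, the classical profile-level analysis is included: per-well
mean feature profiles of the T(+) and T(-) populations, B-score plate
correction, and the Mahalanobis distance of each profile from the
distribution of all profiles, with a Q3 + 3 × IQR fence on control T(+)
distances.

* **B-score** is implemented as two-way Tukey median polish on the plate's
  well grid (row/column median sweeps to convergence), with residuals
  scaled by 1.4826 × the median absolute residual of the plate. A constant
  plate returns zeros, not NaN. Median polish fixed points are not unique:
  B-scores are exactly invariant to per-row constant shifts and to fully
  additive noiseless plates, but a constant added to one column can move
  the converged residuals slightly. This is a property of median polish
  itself, not of the implementation.
* **Covariance regularization.** With more features than profiles the
  sample covariance is singular, so distances use a shrinkage estimate:
  off-diagonal correlations are shrunk toward zero with the analytic
  variance-of-correlations intensity, variances kept unshrunk; a
  pseudo-inverse is the fallback if the matrix is still singular. An
  unregularized mode (`shrinkage = "none"`) exists for well-conditioned
  inputs and is the one with exact affine equivariance.

## Library-design rules

The guide-selection and deconvolution rules of the screen's library
construction are implemented literally:

* exon regions that are first or last in **more than 25%** (strict) of the
  transcripts containing them are avoided;
* candidate guides need an on-target score of **at least 0.7**
  (inclusive), one guide per exon region, preferring guides shared by more
  transcripts, then higher score, then lexicographic id; if too few
  candidates pass, the remaining slots fall back to the highest-scoring
  eligible-region candidates regardless of coverage;
* a colony well is retained when **at least 50** (inclusive) mapped reads
  were found and the top guide is **more than 5×** (strict) as abundant as
  the runner-up; re-araying keeps, per guide, the well with the most
  top-guide reads.

The terminal-exon fraction's denominator is the number of transcripts
*containing* the region (the wording is ambiguous; this reading makes the
rule well-defined for regions absent from some transcripts).

## The synthetic-screen generator

Real raw images for this analysis are not redistributable at package
scale, so every stage is exercised against `generate_screen()`, which
draws screens with exactly the structure the method assumes:

* per well, a Poisson cell count (default mean 2000); each cell T(+) with
  the transfection rate (default 0.5);
* in targeting wells, each T(+) cell is truly perturbed with probability
  `penetrance` (default 0.6) — the latent status is returned in a truth
  table;
* wild-type features are independent standard normal; perturbed cells are
  shifted by `effect_vector` (in wild-type SD units; default a 3-SD shift
  on one feature); control wells have zero effect;
* technical structure is additive: a per-well Gaussian offset
  (`well_sigma`, default 0.2 SD) plus linear row/column plate gradients;
* wells live on a 16 × 24 grid with the outer two columns unused, and a
  deterministic stripe of wells (default fraction 0.25) carries
  non-targeting controls;
* every well has its own random substream keyed by
  `(seed, plate, well)`, so adding wells never changes existing ones and
  identical configs are byte-identical.

What the generator does **not** emulate: correlated features, non-Gaussian
feature distributions, segmentation errors, misclassified transfection
labels, intensity-dependent effects, or spatially correlated well noise
beyond the additive terms. Tests passing on this generator therefore
demonstrate that the pipeline's statistics behave as designed under the
model's own assumptions — not that the assumptions hold for any particular
real screen.

## Numerical and degenerate-input policy

* Features with a T(-) SD at or below `sd_epsilon` (default 1e-8) in any
  well are dropped screen-wide, keeping one feature space for the pooled
  PCA.
* PCA component signs are fixed (largest-magnitude loading positive) so
  results are reproducible across BLAS implementations.
* Strict inequalities everywhere a printed rule says "more than"; gates
  and fences use strict `>`.
* Quantiles are linear-interpolation (type 7) order-statistic quantiles.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; per-well substreams make results independent of well order.

## Problem sizes used by the test-suite properties

The package's property suites run on simulated screens sized for quick
iteration while preserving the study's design points: 2000-cell wells for
score-formula checks; a penetrance grid {0.2, 0.4, 0.6, 0.8} at a 3-SD
effect with 10 bootstraps per well; twenty 96-well all-control screens at
800 cells per well with 5 bootstraps of 250 cells per class for null
calibration of the hit fence; a 3-gene × 2-guide screen at 1500-cell wells
for the replicate-correlation property; and a 36-well interleaved screen
with unit well-level offsets for the within- versus between-well
sensitivity comparison. The screen-scale defaults (100 bootstraps, 500
cells per class) remain the package defaults and are what
`scripts/acceptance.R` runs.

## Known limitations

* The classification score saturates at 0.5; very strong perturbations
  with different penetrance are better distinguished by the gated fraction
  or the KS phenotypic score than by the score itself.
* Balanced 500/500 resampling makes the score a balanced-error transform;
  it does not estimate the well's true class-imbalanced error.
* The PV gate assumes control PVs are approximately unimodal; a
  contaminated control set shifts the gate.
* B-score correction assumes perturbation effects are spatially sparse on
  the plate; blocks of similar perturbations in one row or column will be
  partially absorbed.
* The hypergeometric enrichment treats annotation terms independently (no
  ontology propagation) and tests over-representation only.

## A minimal run

```{r example, eval = FALSE}
scr <- generate_screen(sim_config(
  wells_per_plate = 12, cells_per_well = 1000, control_fraction = 0.4,
  effect_vector = c(3, rep(0, 19)), penetrance = 0.6, seed = 1
))
cfg <- pipeline_config(pca_k = 10, n_boot = 20, n_per_class = 300,
                       min_tpos = 100, seed = 1)
res <- run_within_well(scr$cells, scr$map, cfg)
head(res$screen)
res$gate
```
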