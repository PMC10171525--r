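---
title: "Consensus gray-matter signatures: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gray-matter signatures: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmsignature)
```

## The problem

Voxel-based association studies regress a behavioral outcome on gray-matter
(GM) density at every voxel of a common template space.  Single-shot maps of
"significant" voxels replicate poorly across samples: which voxels survive
depends strongly on which subjects happened to be included.  `gmsignature`
implements a subsampling-consensus remedy: run the voxelwise analysis in many
random subsets of a discovery cohort, keep only cluster-level-significant
voxels in each subset, and retain the voxels selected by a large fraction of
subsets.  The consensus regions then feed a single *signature variable* used
as a one-column brain summary in outcome models, which can be validated in
held-out cohorts against standard anatomical-ROI competitors.

## The procedure, stage by stage

**Voxelwise GLM.** At each analysis-mask voxel $v$, ordinary least squares of
the outcome $Y$ on $[1,\; g_v,\; \mathrm{age},\; \mathrm{gender},\;
\mathrm{education}]$, where $g_v$ is GM density at $v$.  The map records the
$t$-statistic of the GM coefficient, with residual df $n - 5$.  The
implementation residualizes $Y$ and every GM column on the covariates once
(Frisch–Waugh) so all voxels are solved with two matrix products; tests
verify exact equality with the per-voxel normal-equation solve.  Voxels with
zero GM variance across subjects are undefined (`NA`), not errors.

**Cluster-size inference.** The thresholded map ($t \ge$ 3, 5, or 7 in the
expected direction) is decomposed into connected clusters.  Significance is
nonparametric: the outcome's nuisance-model residuals are permuted
(Freedman–Lane), the map is recomputed under each permutation, and the
maximal suprathreshold cluster size is recorded; observed clusters whose
size reaches the 95th percentile of this null (inclusive) are retained.
Each $t$-level gets its own null distribution.

**Consensus.** The retained-cluster masks from $K$ random discovery subsets
(production default $K = 40$ subsets of 400, drawn without replacement
within each subset, independently across subsets) are summed into an overlap
frequency map per $t$-level.  The consensus mask keeps voxels present in at
least 70% of subsets — a count threshold of $\lceil 0.7K \rceil$, i.e. 28 of
40.

**Signature variable.** With per-subject mean GM in the three consensus
masks, the signature regression is
$Y = \beta_0 + \beta_1\,\mathrm{TsROI}_1 + \beta_2\,\mathrm{TsROI}_2 +
\beta_3\,\mathrm{TsROI}_3$, and $S$ is its vector of fitted values in the
target set.  Outcome models are then compared by adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$: demographics-only; demographics plus a
single anatomical ROI mean; demographics plus four ROI means ("FourROIs");
and demographics plus $S$.

**Validation.** Two signature mask sets are compared by fitting both in each
of many random subsets of a validation cohort (default 50 subsets of 200)
and examining the paired adjusted $R^2$ values: Pearson correlation,
identity-line scatter, and Bland–Altman bias with t-based confidence
interval.  Superiority over a competitor is assessed by bootstrap
(subjects resampled with replacement, both models refit per resample,
percentile intervals of the adjusted-$R^2$ difference at 80/90/95/99%; an
interval entirely above zero flags superiority at that level).

## The synthetic-data generator

Real GM volumes and psychometric scores cannot ship with the package, so
every claim is exercised on simulated cohorts with known ground truth:

* a smooth positive template field (baseline density ≈ 1);
* subject volumes = template + (planted effect size × subject latent trait)
  inside one or more box/sphere regions + spatially smoothed Gaussian noise;
* outcome = `outcome_sign` × (loading × latent) + demographic effects +
  noise, with `outcome_sign = -1` emulating inverse-scored everyday-function
  (ECog-like) outcomes whose brain associations are negative;
* diagnosis categories (CN / MCI / Dementia) cut from outcome severity
  tertiles.

Defaults are the package's calibrated study conditions, frozen after a pilot
and used unchanged by the test suite: cohorts of 400 on a $24^3$ grid, one
$7^3$ planted box with effect size 0.06 GM-units per unit latent trait,
voxel noise sd 0.1 with a 1-voxel Gaussian smoothing kernel (smoothing is
what makes cluster-size nulls nontrivial), unit latent loading, outcome
noise sd 0.8, ages uniform on [55, 90], education ≈ N(16, 2.5²) rounded and
clipped to [8, 20], 55% female.  Under these conditions the per-voxel
planted $t$ is ≈ 6 at $n = 200$, so consensus discovery recovers the box
essentially exactly (Dice ≈ 1 at $t = 3$) while $t = 7$ masks remain sparse
— a regime that separates the three levels the way real data does.

What the generator does **not** emulate: scanner/site effects, registration
error, longitudinal change, non-box effect geometry, and spatially varying
noise.  Passing tests therefore demonstrate the machinery's correctness and
calibration, not performance on any real cohort.

## Numerical and design choices

* **Thresholding direction.** Signed thresholding in the expected direction
  is the default (`positive` for positively scored outcomes, `negative` for
  inverse-scored ones); `absolute` is available.  The choice is a
  configurable parameter logged per run.
* **Connectivity.** Cluster adjacency defaults to 26 (vertex) connectivity;
  6 and 18 are available.  Components are computed via an edge list over
  mask voxels and `igraph::components`, and are checked against an
  independent flood-fill oracle.
* **Permutation scheme.** Freedman–Lane by default: permuting nuisance-model
  residuals preserves the age/gender/education structure; raw outcome
  shuffling is available for comparison.  Nulls are reproducible from one
  seed; one master seed spawns per-subset and per-level sub-seeds so any
  piece can be recomputed independently (and in parallel) with identical
  results.
* **Retention quantile.** The cluster-size threshold is the smallest null
  value with at least $(1-\alpha)\,n_{\mathrm{perm}}$ null values at or
  below it, and retention is inclusive (`size >= threshold`).  Calibration
  under the null generative model lands within Monte-Carlo error of the
  nominal 5% (the acceptance script recomputes this each run).
* **Small-n verification.** Production analyses require $n \ge 10$ and
  $n >$ predictors + 2.  The permutation engine exposes `min_n` so that
  exhaustive-enumeration checks (all $n! = 720$ permutations at $n = 6$,
  against seeded no-duplicate draws) can run with a reduced covariate set.
* **Refit vs frozen signatures.** $S$ is refit within each target set by
  default ("refit"), matching the reading that the signature regression is
  computed in the set of interest; a frozen-coefficients mode (fit once,
  apply elsewhere) is provided and labeled, since either reading is
  defensible.  Within small subsets a rank-deficient TsROI design falls
  back to the (unique) least-squares fitted values.
* **Empty masks.** A consensus mask may be empty at some $t$-level at small
  discovery sizes; the signature regression then simply drops that term
  (with a warning).  Collinear mask means trigger a flagged minimum-norm
  pseudo-inverse solve.
* **Dice conventions.** The standard Dice $2|A \cap B| / (|A| + |B|)$ is the
  default; the union-denominator variant $2|A \cap B| / |A \cup B|$ that
  appears in parts of the literature is available as `definition = "union"`.
  Neither is endorsed as "the" convention; they are both implemented and
  named.
* **Mask-set η².** Two signature mask sets are compared through a coded
  volume (0 outside, else the highest $t$-level containing the voxel), so
  the score is sensitive to correspondence of $t$-level locations; Dice uses
  the outermost ($t \ge 3$) masks.
* **Bootstrap CI type.** Percentile intervals by default, with BCa as an
  option; both models are refit inside every resample, and degenerate
  (rank-deficient) resamples are redrawn with a logged count.
* **Bland–Altman CI.** The bias CI is t-based; limits of agreement are
  bias ± 1.96 sd of the differences.
* **Complete-case handling.** A subject missing the current outcome or any
  covariate is dropped for that analysis only; exclusion counts are
  reported.  Gender is coded 0/1 (reference = male), education stays in
  years.
* **Indexing.** All voxel coordinates and linear indices are 1-based, R's
  native convention, used consistently across masks, cluster sets, and
  provenance.

## Problem sizes in the test suite

The package's own test and acceptance runs use deliberately scaled problem
sizes chosen to exercise every code path at desk scale: $16^3$ null cohorts
of $n = 60$ with 500 permutations × 200 datasets for error calibration;
$24^3$ planted-box cohorts of $n = 400$ with 10 discovery subsets of 200 and
200 permutations per level for recovery and replication; 50 validation
subsets of 200 for agreement; a few hundred bootstrap resamples for interval
properties.  Production defaults (40 × 400, 2000 permutations, 10,000
resamples) are the configured starting point of `consensus_config()` /
`run_config()`.

## Known limitations

* Cluster inference offers only cluster-size FWER control — no TFCE,
  voxel-level FWER, or parametric random-field theory.
* No image preprocessing: volumes must already live on a common template
  grid (no registration, segmentation, or resampling).
* The signature model is plain OLS; no regularized or cross-validated
  prediction, and adjusted $R^2$ is the only fit metric.
* Atlas handling accepts any integer label volume; no atlas construction or
  deformation.
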