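# gmsignature

Consensus gray-matter brain signatures from subsampled voxelwise discovery.

## What problem this solves

Voxel-based brain–behavior association maps are notoriously unstable: rerun
the same voxelwise regression on a different draw of subjects and a
different set of "significant" voxels survives.  `gmsignature` is for
researchers who want *replicable* gray-matter (GM) signatures of a
behavioral outcome (e.g. episodic memory or informant-rated everyday
cognition) from cohorts of a few hundred to a few thousand subjects with GM
density volumes in a common template space.

The method:

1. **Discovery subsets.** Draw K random subsets of the discovery cohort
   (default 40 subsets of 400, without replacement within each subset).
2. **Voxelwise GLM.** In each subset, regress the outcome on GM density at
   every analysis-mask voxel, controlling for age, gender, and education;
   keep the t-statistic of the GM coefficient.
3. **Cluster-size permutation inference.** Threshold the t-map at t = 3, 5,
   7; retain clusters whose size reaches the 95th percentile of a
   permutation null of maximal cluster size (Freedman–Lane residual
   permutation, default 2000 iterations, separate null per t-level).
4. **Consensus.** Sum the per-subset masks into overlap frequency maps and
   keep voxels selected by ≥ 70% of subsets — the consensus TsROI masks.
5. **Signature variable.** Regress the outcome on the per-subject mean GM in
   the three consensus masks,

   Y = β₀ + β₁·TsROI₁ + β₂·TsROI₂ + β₃·TsROI₃,

   and take the fitted values S as a one-column brain summary.  Outcome
   models Y ~ S + age + gender + education are scored by adjusted
   R² = 1 − (1 − R²)(n−1)/(n−p−1) and compared against demographics-only
   and anatomical-ROI competitor models ("FourROIs": amygdala, entorhinal,
   hippocampus, caudate) via bootstrap confidence intervals on adjusted-R²
   differences, paired validation-subset fits, and Bland–Altman agreement.

A synthetic-cohort generator with planted effect regions provides ground
truth, so the whole pipeline is testable without any imaging download.
Spatial agreement tools (Dice, η², atlas-overlap tables) compare signature
masks across cohorts.

## Worked example

Simulate a discovery cohort with a planted 6³ effect box, discover consensus
masks, and validate the signature in an independently simulated cohort:

```r
library(gmsignature)

cfg <- generative_config(n_subjects = 200, shape = c(16, 16, 16),
  effects = list(effect_spec("box", lo = c(6, 6, 6), hi = c(11, 11, 11),
                             effect_size = 0.1)),
  seed = 11)
sim  <- simulate_cohort(cfg)
mask <- make_analysis_mask(sim$template, 0.3)

res <- run_consensus_discovery(sim$cohort, sim$volumes, mask, "memory",
  consensus_config(k_subsets = 8, subset_size = 100,
                   t_levels = c(3, 5, 7), n_perm = 200, seed = 11))
res$mask_set
#> <signature_mask_set> t-levels 3/5/7; voxel counts 216/213/60
dice(res$mask_set$masks$t3, sim$truth)
#> [1] 1
```

The t = 3 consensus mask recovers the 216-voxel planted region exactly
(Dice = 1); the t = 7 mask keeps only the strongest 60 voxels.  Validation
in a fresh cohort from the same generative truth:

```r
val <- simulate_cohort(generative_config(n_subjects = 200,
  shape = c(16, 16, 16),
  effects = list(effect_spec("box", lo = c(6, 6, 6), hi = c(11, 11, 11),
                             effect_size = 0.1)),
  seed = 12))

signature_fit(val$cohort, val$volumes, res$mask_set, "memory")$fit
#> <fit_result> signature: n = 200, p = 4, R2 = 0.5256, adj R2 = 0.5158
fit_outcome_model(val$cohort, "memory", c("age", "gender", "education"),
                  label = "demographics")
#> <fit_result> demographics: n = 200, p = 3, R2 = 0.0668, adj R2 = 0.0525

means <- roi_mean_vector(val$volumes, res$mask_set,
                         subject_ids = val$cohort$subject_id)
bootstrap_r2_difference(cbind(val$cohort, means[, -1]), "memory",
                        competitor = character(0), n_boot = 1000, seed = 13)
#> <bootstrap_r2_result> observed diff 0.4633 (1000 resamples, percentile)
#>  level     lower     upper superior
#>   0.80 0.3870319 0.5318929     TRUE
#>   0.90 0.3723041 0.5516060     TRUE
#>   0.95 0.3570803 0.5671725     TRUE
#>   0.99 0.3354730 0.5986793     TRUE
```

The signature model explains 0.52 of outcome variance (adjusted) against
0.05 for demographics alone, and the bootstrap intervals of the
adjusted-R² difference sit entirely above zero at every level — the
signature is superior even at the 99% level under these planted-signal
conditions.

A thin command-line wrapper over the same pipeline lives at
`inst/cli/gmsig.R` (stages `simulate`, `discover`, `consensus`, `fit`,
`validate`, `compare`, `similarity`, configured by YAML); see the vignette
in `vignettes/consensus-signatures.Rmd` for the full model description and
design notes.

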