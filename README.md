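# lungcv

Quantifying ventilation inhomogeneity in 3D lung SPECT with sliding-kernel
coefficient-of-variance (CV) maps and the AUC(CV_T) score.

## What problem this solves

Early chronic obstructive pulmonary disease (COPD) reduces ventilation
regionally. In a Technegas ventilation SPECT image this appears not as a
readable lesion but as increased *texture*: the reconstructed activity
distribution becomes inhomogeneous. `lungcv` is for imaging scientists who
want a single, reference-anchored number for that inhomogeneity:

* a cubic kernel (3 × 3 × 3 cm³ by default) slides voxel-by-voxel through
  the segmented, edge-peeled lung and stores the local coefficient of
  variance, CV = 100·σ/μ (%), at each position — the **CV matrix**;
* the CV values are histogrammed in 1 %-wide bins normalised to a total
  area of 100 % — the **frequency function**;
* the threshold **CV_T** is the modal value of the mean frequency function
  of a healthy reference group;
* the score **AUC(CV_T)** is the percentage of all CV values strictly above
  CV_T. Healthy lungs score ≈ 50 % by construction; inhomogeneous lungs
  score up to 100 %.

The package also contains a complete synthetic validation chain — two-lung
digital phantom with spherical hypo-ventilated lesions (nine standard
distributions spanning 1–2 cm lesions, 0–50 % relative activity, 10–48 %
occupancy, even or clustered placement), idealised parallel-beam projector
with Gaussian system blur, clinical count budgets with Poisson noise, OSEM
reconstruction (10 iterations × 16 subsets) with 3D Butterworth
post-filtering (0.5 cm⁻¹, order 3), lung segmentation with edge peeling,
and Mann–Whitney group statistics — so the whole normal-versus-COPD
discrimination experiment runs self-contained on a desk.

## Worked example

```r
library(lungcv)

plan <- experiment_plan(
  distributions = copd_distributions()[c("uniform", "1cm_50pct_10_even")],
  realisations = 20L, seed = 1L)
result <- run_experiment(plan)
result
#> <experiment_result> CV_T = 20.5%, 20 realisations
#>   uniform              mean AUC 59.8% +/- 1.7 (95% CI)
#>   1cm_50pct_10_even    mean AUC 64.3% +/- 1.8 (95% CI), p vs normal = 0.000292
```

What the numbers mean: the healthy reference group defines a CV threshold
of 20.5 % (the mode of its mean CV frequency function) and scores a mean
AUC(CV_T) of 59.8 % against its own threshold — roughly half of a unimodal
distribution lies above its mode, plus a sub-bin alignment offset discussed
in the methods vignette. The lesioned lung — 1 cm lesions at 50 % activity
in 10 % of the lung, i.e. a 5 % total ventilation reduction that is
invisible to the eye in the reconstruction — shifts its CV distribution
right and scores 64.3 %; the Mann–Whitney test separates the two groups of
20 noise realisations at p ≈ 3e-4. Larger or emptier lesions separate by
far more (2 cm distributions reach AUC 78–99 %).

Group statistics for a human cohort work the same way:

```r
tab <- reference_cohort()          # published AUC values, 5 healthy + 5 COPD
group_summary(tab$auc[tab$group == "healthy"])   # mean 65.4, 95% CI ± 12.7
mann_whitney_u(tab$auc[tab$group == "healthy"],
               tab$auc[tab$group == "copd"])     # exact p = 2/252 ≈ 0.0079
```

A thin command-line front end is installed with the package
(`system.file("cli", "lungcv", package = "lungcv")`) with subcommands
`phantom`, `cv`, `experiment` and `compare`.

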