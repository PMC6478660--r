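# petez — epileptogenic-zone localization from interictal FDG-PET

`petez` implements single-subject statistical parametric mapping of
interictal FDG-PET for presurgical epilepsy work-up.  In medically
refractory epilepsy the epileptogenic zone (EZ) is typically hypometabolic
between seizures; comparing one patient's spatially and
intensity-normalized PET voxel-by-voxel against a normative control cohort
turns that deficit into a t-map whose supra-threshold clusters propose the
EZ.  The package is aimed at imaging methodologists and epilepsy
researchers who want the whole chain — preprocessing, mapping, *dynamic*
(p, k) segmentation, side/sublobar EZ calls, and the agreement statistics
used to validate such a tool against surgical outcomes — as scriptable,
tested R functions.

## The statistic at the core

For a patient study `y` and `n` preprocessed controls with per-voxel mean
`x̄` and unbiased variance `s²`, each in-mask voxel gets the two-sample
pooled-variance Student statistic with a singleton first group,

```
t = (x̄ − y) / sqrt(s² (1 + 1/n)),    df = n − 1
```

(sign convention: positive t = hypometabolism).  The map is thresholded at
a one-sided level p — uncorrected, or Bonferroni-corrected over the m
in-mask voxels — and 26-connected components of at least k voxels become
clusters.  Components that are mostly non-cortical or mostly within 6 mm
of the interhemispheric plane are excluded; remaining clusters are ranked
by (size, peak t), and the top cluster's majority atlas labels yield the
EZ call, e.g. `L/MT` (left mesial temporal), with a combined `MLT` class
when mesial and lateral temporal cortex are both involved.  Because the
t-map is computed once, re-thresholding the whole default 6 × 4 grid of
(p, k) combinations is nearly free — that sweep is the package's
replacement for interactive scrollbar-driven segmentation.

Preprocessing follows the dedicated-pipeline recipe: 12-parameter affine
normalization to a PET template (multi-resolution least squares), optional
application of a precomputed nonlinear deformation field, quotient-histogram
**parabola** intensity normalization (the global factor is the mode of the
patient/reference quotient distribution, robust to the very hypometabolism
being sought), and 8 mm FWHM Gaussian smoothing.  An `spm-emulation` mode
swaps in proportional scaling and a 30%-of-maximum background mask.

## Worked example

Evaluation of a 30-patient validation table (packaged fixture; one row per
patient with the surgically confirmed EZ and each method's call):

```r
library(petez)
tab <- load_study_table(study_table_fixture())
evaluate_study(tab)$summary
#> # A tibble: 5 × 8
#>   method          n positive negative localizing non_localizing positive_pct
#> 1 visual         30       28        2         21              7        93.3
#> 2 spm1           30        1       29          0              1         3.33
#> 3 spm2           30       18       12         11              7        60
#> 4 petanalysis    30       30        0         21              9       100
#> 5 mri            30       16       14         16              0        53.3

d <- discordant_counts(tab, "visual", "spm2")
mcnemar_exact(d$b, d$c)$p_value
#> visual vs SPM2 discordants b = 14, c = 4, exact McNemar p = 0.0309
```

`positive` counts studies with any supra-threshold cluster (for MRI:
lesional studies); `localizing` counts those whose call matches the
reference EZ on side and sublobar class.  Visual reading and the dynamic
analysis localize about two thirds of patients, the fixed uncorrected SPM
threshold (`spm2`) about one third, and the corrected one (`spm1`) almost
none — the behavior the dynamic sweep is designed to overcome.  The exact
McNemar p = 0.0309 says the visual-vs-SPM2 difference is unlikely to be
chance.

Imaging pipeline on a synthetic phantom with a known lesion
(left mesial-temporal, 20% contrast):

```r
out <- file.path(tempdir(), "demo")
spec <- phantom_spec(shape = c(32, 32, 32), brain_semiaxes = c(34, 36, 32),
                     blob_radius = 7, lesion_radius = 2.5)
sim <- cmd_simulate(spec, out = out, seed = 1)
cfg <- jsonlite::read_json(file.path(out, "config.json"), simplifyVector = TRUE)
cfg$k_grid <- c(10, 20, 30, 40); cfg$report_k <- 20
res <- cmd_analyze(cfg)
#> ground truth: L/MT   EZ call: L/MT
res$sweep
#> # A tibble: 24 × 7
#>       p     k t_threshold n_clusters largest peak_t ez
#> 1  0.05    10        1.73          1      92   9.72 L/MT
#> 2  0.05    20        1.73          1      92   9.72 L/MT
#> 5  0.01    10        2.54          1      91   9.72 L/MT
#> ...
```

Each sweep row is one (p, k) segmentation: the t threshold it implies, how
many clusters survive, the largest cluster's size and peak t, and the EZ
call — here the seeded lesion is recovered at every setting.
`autoplot(res$sweep)` draws the grid as a tile map; `plot_tmap_slice()`
shows the t-map itself.  A thin command-line front-end over the same
functions ships at `inst/cli/petez.R`
(`Rscript petez.R simulate|analyze|evaluate ...`).

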