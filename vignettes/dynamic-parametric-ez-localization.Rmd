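---
title: "Dynamic single-subject parametric mapping for epileptogenic-zone localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic single-subject parametric mapping for epileptogenic-zone localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In medically refractory epilepsy, resective surgery can be curative when the
epileptogenic zone (EZ) — the cortical region whose removal abolishes
seizures — is localized correctly before the operation.  Interictal FDG-PET
contributes to this work-up because the EZ is typically *hypometabolic*
between seizures, but visual reading misses subtle deficits.  The remedy is
statistical parametric mapping: compare the patient's spatially and
intensity-normalized PET, voxel by voxel, against a normative control
cohort, and look for clusters of significantly reduced uptake.

Generic neuroimaging packages make this possible but slow and rigid: each
(significance level, cluster extent) combination is a separate batch run.
The approach implemented here makes segmentation *dynamic*: the t-map is
computed once, and re-thresholding over a whole grid of
(p, k) combinations is nearly free, so an observer (or a script) can sweep
from liberal to strict settings in one session.  `petez` implements that
pipeline, the side/sublobar EZ call derived from it, the evaluation
statistics used to validate it against a surgical gold standard, and a
synthetic phantom that makes every stage testable without any patient data.

## The processing model

For a patient study $y$ and controls $x_1, \dots, x_n$ on a common grid:

1. **Spatial normalization.**  A 12-parameter affine (3 translations,
   3 rotations, 3 scales, 3 shears; order `T.Rz.Ry.Rx.S.H`) is estimated by
   multi-resolution least squares against a PET template
   (`affine_register()`), with deterministic center-of-mass initialization.
   Both images are Gaussian-smoothed before cost evaluation (default 8 mm)
   because piecewise-flat PET-like intensities otherwise give the optimizer
   thin-shell gradients.  Nonlinear refinement is *consumed*, not produced:
   `apply_deformation()` applies a precomputed displacement field (mm,
   pull-back), as such fields are the business of dedicated registration
   tools.
2. **Intensity normalization.**  The dedicated method
   (`intensity_normalize_parabola()`) estimates one global scale factor as
   the mode of the voxel-wise quotient $y/\mathrm{ref}$ over the analysis
   mask: quotients are histogrammed between their 1st and 99th percentiles
   into 100 equal bins, and a parabola is least-squares fitted around the
   modal bin (± 3 bins); the factor is the vertex abscissa.  The mode is
   insensitive to the focal hypometabolism the analysis is hunting — a
   total-counts ratio is not, which is exactly the bias this method removes
   (the package demonstrates this with a 10% hot-spot contamination test).
   The SPM-style alternative (`intensity_normalize_proportional()`) divides
   by the masked mean over a nominal grand mean of 50.
3. **Smoothing.**  Separable Gaussian, FWHM 8 × 8 × 8 mm
   ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ voxels after division by the
   spacing), kernel truncated at $4\sigma$ and renormalized to sum 1, zero
   padding at the grid edge.
4. **t-map.**  A two-sample pooled-variance Student test with a singleton
   first group:
   $t = (\bar{x} - y)\,/\,\sqrt{s^2 (1 + 1/n)}$, $\mathrm{df} = n - 1$,
   computed over the analysis mask.  The sign convention is
   hypometabolism-positive.  Zero-variance voxels get $t = 0$ (they are
   degenerate background, and must not seed clusters); their count is
   reported.
5. **Dynamic segmentation.**  `threshold_sweep()` re-thresholds the map at
   every (p, k) of the grids (defaults
   p ∈ {0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001}, k ∈ {50, 100, 150, 200}
   voxels — grid points chosen inside the published dynamic ranges),
   extracts 26-connected components, applies the anatomical exclusions,
   ranks clusters, and emits one EZ call per combination.

Two analysis modes bundle these choices: `petanalysis` (gray-matter mask
from the label atlas + parabola normalization) and `spm-emulation`
(background mask at 30% of the image maximum + proportional scaling), the
latter optionally with Bonferroni family-wise correction.

## EZ calling rules

* **Exclusions** (in order): components smaller than k voxels; components
  with more than half their voxels on non-cortical labels (seizures arise
  in cortex); components with more than half their voxels within 6 mm of
  the interhemispheric plane (x = 0), where spill-over between hemispheres
  is not anatomically meaningful.  The 50% vote and the 6 mm margin are
  explicit, configurable choices — the underlying clinical rule is stated
  qualitatively in the literature.
* **Ranking**: size descending, then peak t, then lexicographic peak-voxel
  index (a total order).  The published rule — "the biggest cluster and
  with the highest statistical significance" — is a composite; size-first
  with a significance tie-break is the only total order in which "biggest"
  leads, and it is kept as a documented interpretive decision rather than a
  hidden constant.
* **Call**: side of the rank-1 cluster's majority label; sublobar class by
  majority vote of its cortical voxels.  If mesial-temporal and
  lateral-temporal labels each hold at least 30% of the cluster, the
  combined class `MLT` is called — without such a rule the combined
  category used in the validation table could never be produced.  The 30%
  share is configurable.
* An empty segmentation is the Negative call.

## Statistical evaluation

`evaluate_study()` reproduces the validation statistics on a per-patient
results table: positive/negative and correctly-localizing counts per method
(visual, two fixed SPM thresholds, the dynamic analysis, MRI), Cohen's
kappa against the surgically confirmed EZ with the verbal bands
(slight/fair/moderate/substantial/excellent at 0.20/0.40/0.60/0.80 cuts;
values falling in the printed cut-point gaps are mapped to the lower band
and flagged), and pairwise *exact* McNemar tests on the discordant pairs,
$p = \min(1,\ 2\,P(X \le \min(b,c)))$, $X \sim \mathrm{Bin}(b+c, 1/2)$.
The exact binomial variant is used deliberately: it is the only McNemar
variant that reproduces both published p-values (0.0309 and 0.0117) from
the table's discordant counts, which doubles as a validation of the match
rule below.

A call *matches* the reference EZ when the sides agree and the sublobar
classes agree, with the combined temporal class `MLT` matched by `MT`,
`LT` or `MLT` (and symmetrically); `MT` versus `LT` is a mismatch, and a
Negative call matches nothing.

**The one-cell erratum.**  The packaged as-printed table yields 21/30
correctly localizing studies for the dynamic analysis under any match rule
consistent with the other printed counts, while the publication reports
20/30 and, in its discussion, lists patient 9 among the incorrect
localizations.  The package therefore ships two fixtures: the as-printed
table and an erratum variant in which patient 9's dynamic-analysis call is
Negative.  The erratum variant reproduces the printed 20/30 and the
printed McNemar p = 0.0117 exactly; the discrepancy is surfaced as data,
not silently patched.

**Kappa values are banded, not recomputed.**  The published kappas
(0.643, 0.622, 0.242, 0.520) depend on an unstated category space (whether
Negative is a category, whether MLT is merged).  The package computes
kappas for its own documented category space and verifies the *bands* of
the published values; it does not pretend to recompute numbers whose
definition is not recoverable.

## The phantom

`phantom_spec()` defines a desk-scale stand-in for a normative database:
a 64³ grid at 2.6 × 2.6 × 2.4 mm (the clinical reconstruction geometry),
an ellipsoidal brain (semi-axes 75 × 80 × 70 mm) whose interior is a
non-cortical core at intensity 60, and ten spherical cortical blobs
(left/right × mesial temporal, lateral temporal, frontal, parietal,
occipital; radius 15 mm; intensity 100) mirror-symmetric about x = 0.
Controls are `template × g + ε` truncated at 0 with a log-normal global
factor ($\sigma_g = 0.15$, a realistic inter-subject global-metabolism
spread) and i.i.d. voxel noise ($\sigma_v = 5$, i.e. 5% of cortical
intensity — enough that single-subject detection at n = 20 controls is
non-trivial after smoothing).  Patients add a spherical lesion (radius 4
voxels ≈ 270 voxels) whose intensity is multiplied by $1 - c$ (default
contrast $c = 0.2$), anchored at a named region with known (side,
sublobar) ground truth, plus an optional random affine misalignment.

What the phantom does emulate: global scale confounds, voxel noise,
focal hypometabolism of configurable size/contrast, misalignment,
left/right anatomy, cortical versus non-cortical tissue.  What it does
not: realistic scanner point-spread and partial-volume effects, spatially
correlated inter-subject anatomical variability, asymmetric physiologic
metabolism, non-spherical lesions.  Passing phantom tests therefore
demonstrates the statistical machinery is correct under its stated model,
not clinical performance on real studies.

## Numerical and design decisions

* **Family-wise correction = Bonferroni** over in-mask voxels.  The
  random-field-theory correction used by generic SPM software is out of
  scope; Bonferroni is exactly testable and reproduces the qualitative
  behavior of corrected thresholds (very restrictive for focal epilepsy
  hypometabolism).  On a 20%-contrast default phantom the lesion is strong
  enough (peak t ≈ 40) to survive even Bonferroni; the restrictive regime
  is therefore exercised where it provably holds — family-wise control on
  lesion-free phantoms, where the corrected 0.05/k = 50 setting yields an
  empty segmentation.
* **One-sided test.**  Hypometabolism only (positive t), matching the
  clinical question; a flag is not exposed because the direction tag is
  part of the t-map type.
* **Quotient reference.**  Whether the quotient distribution should be
  taken against the template or the control mean is not specified in the
  source material; the pipeline uses the control-cohort mean (each control
  is first normalized against the template), selectable via the
  `reference` argument of `analyze_patient()`.
* **Connectivity 26** by default (most inclusive; clusters never split on
  diagonals), switchable to 6 or 18; all three are checked against a
  breadth-first-search oracle.
* **df convention**: the singleton patient group contributes no variance
  degrees of freedom, so df = n − 1 for n controls.
* **Histogram defaults** for the parabola fit: 100 bins, ±3-bin window —
  stable mode estimates for 10⁴–10⁶ masked voxels.  Degenerate histograms
  (all quotients in one bin) and upward-opening parabolas fall back to the
  modal bin center with a flagged warning.
* **Zero padding** for smoothing, with masks re-binarized at 0.5 after
  resampling; intensity near the grid edge is attenuated, which is
  immaterial here because analysis masks keep well inside the field of
  view.
* **Registration** cost is plain SSD (same-modality PET to PET template);
  mutual information would add cost and nothing else.  Optimization is
  Nelder-Mead then BFGS over a 3-level pyramid with the iteration budget
  concentrated at the coarse levels; everything is deterministic for fixed
  inputs.

## Problem sizes used by the test-suite experiments

The package's statistical claims are exercised at sizes a reviewer can run
at a desk: t-map equivalence against a brute-force per-voxel t-test on 100
random 6³ grids; type-I calibration from 200 null phantom draws on a 32³
grid (about 2 × 10⁶ voxel-level null tests per significance level);
connected-component equivalence on 50 random 16³ volumes; end-to-end
lesion recovery and false-positive rates on 50 + 50 phantoms at the full
64³ geometry; scale-equivariance of the intensity normalization over 20
phantom seeds.  These sizes were chosen as the smallest at which the
binomial error bars are decisive for the stated tolerances.

## Known limitations

* The affine registration is a generic SSD optimizer adequate for the
  phantom's geometry; clinical spatial normalization should use a
  dedicated registration tool and enter the pipeline as a precomputed
  deformation field.
* Bonferroni is more conservative than random-field corrections at
  matched nominal levels; corrected-mode results are comparable in kind,
  not in exact threshold.
* The evaluation module treats the study table as ground truth; it has no
  notion of observer consensus or confidence levels beyond the categories
  recorded there.
* Covariates (age, sex) are not modeled in the t-map design.
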