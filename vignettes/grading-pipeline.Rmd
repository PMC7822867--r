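---
title: "Texture radiomics for grading peripheral zone prostate cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics for grading peripheral zone prostate cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pzgrade)
```

## The problem

Prostate cancer aggressiveness is graded histologically (ISUP grade groups
1-5), but biopsy sampling is invasive and spatially limited. T2-weighted
(T2W) MRI offers high-resolution anatomical contrast whose signal is,
however, not quantitative: intensities drift between scanners and sites.
This package implements a pipeline that turns masked tumor volumes from
multi-site T2W and diffusion-weighted (DW) MRI into quantitative features
— first-order histogram statistics and grey level co-occurrence (GLCM) /
run length (GLRLM) texture descriptors — and evaluates how well they
separate low-aggressive (grade group 1) from intermediate/high-aggressive
(grade group >= 2) peripheral zone cancers when a linear SVM trained at
some institutions is tested at a held-out institution.

The biological premise is that aggressive tumors lose glandular
organisation, which should appear in imaging as reduced textural
homogeneity (lower angular second moment, inverse difference moment) and
increased disorder (higher entropy), alongside a lower apparent diffusion
coefficient (ADC) in denser tissue.

## Pipeline stages and their models

### Dual-reference pseudo-T2 normalization

Raw T2W intensities are mapped through the unique affine transform that
sends a fat reference intensity (90th percentile of a fat region) to the
literature T2 of fat at 3T and a muscle reference intensity (10th
percentile) to the T2 of muscle. Because site/scanner effects that are
affine in intensity are absorbed into the measured references, the mapping
removes them exactly on noise-free data — a property the test suite checks
to 1e-10 over random gains in [0.5, 2] and offsets in [-100, 100]. The
anchor values default to `t2Fat = 121` ms and `t2Muscle = 40` ms, typical
3T literature values; both are configuration parameters because reported
literature values vary by sequence and study. ADC values are never
normalized: they are quantitative by construction.

Detection of fat and muscle regions is out of scope: reference intensities
are inputs. Bias-field correction is likewise treated as an optional,
externally applied preprocessing step; the synthetic data are bias-free.

### Outlier exclusion

Within each tumor volume of interest (VOI), voxels outside
[mu - 3 sigma, mu + 3 sigma] are excluded, where mu and sigma are the mean
and SD of the VOI's own intensities — a single pass with no re-estimation.
The SD convention is the sample SD (n - 1); a configuration switch selects
the population SD, and the two differ negligibly at typical VOI sizes
(hundreds of voxels). The rule is applied to both the normalized T2W
values and the ADC values. On Gaussian data it removes ~0.3% of voxels.

### ADC mapping

ADC is the negative slope of an ordinary least squares fit of ln S(b) on b
using the nonzero b-values only (100, 400, 800 s/mm^2). The b = 0 frame is
excluded so that fast pseudo-diffusion (perfusion) signal, which decays
almost completely by b = 100, cannot bias the estimate; the tests
demonstrate this on a biexponential signal. The fit is unweighted; a
voxelwise nonlinear least-squares variant is available
(`fitAdcMap(..., method = "nls")`) and agrees with the log-linear fit to
well under 2% on low-noise signals. Voxels with any nonpositive intensity
get ADC = 0 and are counted in a QC attribute.

### Quantization and texture matrices

VOI intensities are discretized into `Ng = 32` equal-width bins (fixed bin
number) spanning the VOI minimum to maximum. The range is computed over
the whole 3D VOI, not per slice, so all slices of a tumor share one grey
scale; the in-VOI maximum maps to level Ng and a constant VOI to level 1.
Fixed-bin-number quantization makes every texture feature invariant to
affine intensity shifts, which the tests verify directly.

GLCMs and GLRLMs are built per axial slice at one-pixel distance in the
four symmetric directions 0, 45, 90 and 135 degrees, with offsets
(0,1), (-1,1), (-1,0), (-1,-1) in (row, column) pixels. Pixel — not
millimetre — distance is used, ignoring the mild in-plane anisotropy.
GLCMs count ordered pairs with both endpoints in the mask, are
symmetrized by adding the transpose and normalized to probabilities.
GLRLM runs are maximal constant-level segments along the direction,
broken by mask boundaries (and by outlier-excluded voxels).

Eighteen GLCM features and eleven GLRLM features are computed per
directional matrix. Entropy-type features use log base 2 with
0 log 0 := 0. Degenerate conventions: a constant slice has correlation 1
and IMC1 = IMC2 = 0; IMC2 is computed base-independently as
sqrt(1 - exp(-2 (HXY2 - HXY))) with entropies converted to nats.

### 2D-average aggregation

Features are averaged across slices within each direction, then across the
four directions. Empty (slice, direction) cells — slices where the mask
admits no pixel pair in that direction — are skipped rather than
zero-filled, and a direction with no valid slice drops out of the outer
mean. When all cells are valid and counts are equal, the nested mean
equals the flat mean over all cells, and a 90-degree rotation of a
square-masked slice leaves the direction-averaged features unchanged
(both verified to 1e-12). This is the per-direction-matrix 2D averaging
variant; toolkits that merge matrices across directions before computing
features will produce slightly different values.

### Association statistics

Each of the 51 feature columns (11 histogram features for each of ADC and
T2W, plus 29 T2W texture features) is tested for association with grade
group by tie-corrected Spearman correlation (two-sided p from the t
approximation) and for low versus intermediate/high separation by a
two-tailed Mann-Whitney U test (exact by enumeration when the combined n
is at most 12 — also correct under ties — and by the tie- and
continuity-corrected normal approximation otherwise). Each statistic's
p-value family is corrected jointly across all features by
Benjamini-Hochberg at FDR 0.05; whether to pool or split the ADC and T2W
families was an open choice and joint correction was adopted as the more
conservative reading.

Association tests run at tumor level, matching how the cohort's class
counts are reported.

### Two-way ANOVA site screen

Before modelling, each feature (log transformed; a positivity shift
x - min + 1 is applied first when any value is nonpositive, since several
features such as cluster shade and skewness can be negative) is fit by
two-way ANOVA with factors institution and aggressiveness class. Type-II
F tests with the full-model residual mean square as denominator (the
`car::Anova` convention, cross-checked in the tests) give the institution
main effect and the institution-by-class interaction; a feature is dropped
when either is significant at 0.05. Sites contributing a single tumor are
merged out of the screen with a warning. In the hold-one-site-out
evaluation the screen is applied to training data only (leakage-free
default); screening once on all data is available for comparison but
leaks the test site's distribution into feature selection. A training
split that cannot support the screen at all — fewer than two training
sites containing both classes, which small imbalanced cohorts do produce
— performs no exclusion and warns, rather than aborting the split.

### Hold-one-institution-out SVM evaluation

Each institution in turn is the external test set; the others train a
linear SVM with inverse-class-frequency sample weights. Training uses
stratified 10-fold cross-validation partitioned at patient level — all
tumors of a patient share a fold — with the misclassification cost C and
the feature subset tuned concurrently: C ranges over seven logarithmically
spaced values from 10^-1 to 10^1, and recursive feature elimination
(dropping the smallest-|weight| feature one step at a time, candidate
sizes k = 1..p) is scored at every size along each (C, fold) elimination
path. The (C, k) pair with the lowest mean balanced validation error wins;
ties prefer fewer features, then smaller C. Balanced error (mean of the
two class error rates) matches the inverse-frequency weighting of the
classifier. Features are z-scored with training-set parameters before
every fit — a linear SVM over features with wildly different scales
(ADC ~ 1e-3, run length non-uniformity ~ 1e2) is otherwise dominated by
scale, so standardization is recorded as part of the model.

The decision threshold is the Youden-index maximizer over the pooled
out-of-fold decision scores of the winning pair, with ties broken toward
higher specificity; it transfers unchanged to the held-out site, where
performance is reported as AUC with DeLong 95% CI, sensitivity
(intermediate/high), specificity (low) and balanced accuracy. Texture
augmentation is assessed per site by DeLong's paired AUC test and across
sites by paired t-tests on AUC and balanced accuracy.

Six feature sets are evaluated: ADC histogram, T2W histogram, T2W texture,
T2W histogram + texture, ADC + T2W histogram, and all three combined.

## The synthetic cohort generator

Patient MRI from the multicenter study the pipeline targets is not
publicly deposited, so the generator produces cohorts with the statistical
structure the analysis assumes:

- **Layout.** Six sites with 17, 15, 21, 16, 8 and 10 patients (87 total);
  ~20% of patients carry a second tumor, giving ~104 tumors; per-site
  low-class proportions mirror the reported imbalanced distribution
  (about 30 low vs 74 intermediate/high overall, with grade groups 2-5
  weighted 36:26:6:6 within the intermediate/high class).
- **Tumor geometry.** Ellipsoidal VOIs with mild shape jitter over 2-5
  axial slices, sized lognormally with mean ~420-470 voxels and clipped to
  101-1397 voxels; voxel spacing 0.625 x 0.625 x 3.6 mm (3 mm slices plus
  gap). Volumes are small tumor-centred crops rather than full 320 x 320
  fields of view: every downstream computation is VOI-local, so full-FOV
  synthesis would only add runtime.
- **Texture model.** Within-tumor T2W texture is a stationary Gaussian
  random field: white noise smoothed by an isotropic Gaussian kernel whose
  width (the correlation length) decreases with grade group — 3.0, 2.5,
  2.0, 1.5, 1.0 pixels for grade groups 1-5 — plus independent noise with
  SD rising 0.3 to 0.7. Longer correlation lengths produce higher angular
  second moment and lower entropy, so the generated classes realize the
  "aggressive = less homogeneous, more disordered" premise as a monotone
  property that the tests verify by trend and sign tests. Only the
  direction of these effects is externally motivated; the magnitudes are
  package defaults chosen to give a clearly separable ("strong effect")
  cohort.
- **Intensity and ADC class effects.** Mean raw T2W tumor level falls
  110 to 70 (arbitrary units) and mean tumor ADC falls 1.30 to 0.75 x
  10^-3 mm^2/s across grade groups 1-5, with per-tumor and per-voxel
  jitter; background ADC is 1.6 x 10^-3 mm^2/s.
- **Site effect.** Each site applies an affine gain/offset to raw T2W
  intensities after texture synthesis (gains 0.8-1.3, offsets -10..20 by
  default). Fat and muscle reference blocks are embedded in volume corners
  with their 90th/10th percentile intensities hitting the configured
  anchors exactly before the site effect; the returned references are
  reported after the site effect, so dual-reference normalization can undo
  it — and does, exactly, in the noise-free case.
- **DW series.** Four frames at b = 0, 100, 400, 800 s/mm^2 following
  S(b) = S0 exp(-b ADC) voxelwise with Gaussian noise (2% of S0 by
  default); Rician noise is available by configuration.
- **Determinism.** The cohort is bit-for-bit reproducible under the same
  (configuration, seed); all internal seeds derive from the one passed in.

A `"null"` configuration switches every class effect off (shared texture,
intensity and ADC parameters across grade groups) for studying classifier
behaviour when nothing is there to find.

### What the generator does not emulate

No anatomy (prostate zones, organ boundaries), no bias fields, no motion
or distortion artifacts, no registration error between T2W and DW (frames
share the T2W grid by construction), no inter-observer variability in
masks, and Gaussian rather than fully realistic MR noise. Consequently,
passing tests demonstrate that the pipeline's statistics and machine
learning behave correctly on data with the assumed structure — they do not
certify performance numbers on real patient MRI, and the study's reported
accuracies cannot be reproduced from synthetic data.

## Numerical choices and degenerate inputs

- Quantization assigns the VOI maximum to level Ng (half-open bins,
  closed at the top); a constant VOI occupies level 1 only.
- Empty co-occurrence cells: a (slice, direction) with no valid pixel pair
  is flagged (`nPairs = 0`) and skipped by aggregation; a VOI with no
  valid cell at all is an error ("VOI too small for texture").
- Degenerate GLCM correlation (zero marginal variance) is defined as 1;
  IMC1 and IMC2 are 0 when the driving entropies vanish.
- sigma = 0 in outlier exclusion keeps all values.
- A constant feature yields Spearman rho = 0 with p = 1 and a degenerate
  flag; zero-variance paired differences yield p = 1 likewise for the
  DeLong comparison and the paired t-test.
- Nonpositive DW intensities zero the voxel's ADC and increment a QC
  count.
- Youden ties break toward the higher threshold (higher specificity).
- Inner-CV fold assignment is seeded and returned with the model so a run
  can be audited.

## Problem sizes used by the test study

The end-to-end acceptance study runs the full six-site strong-effect
cohort (87 patients, ~104 tumors, all six feature sets) once, and twenty
replicates of a null cohort scaled to three sites of eight single-tumor
patients with only the T2W histogram / histogram+texture pair — the
augmentation comparison the null question concerns. These sizes are the
package's chosen defaults for its own simulation study; the generator
accepts any layout.

On the null replicates, "no significant augmentation effect" is judged by
one BH family per replicate over the per-site DeLong p-values and the two
across-site paired t-tests, at 0.05.

## Known limitations

- The 2D-average texture variant is implemented literally (features per
  directional matrix, then nested means); IBSI-style merged-matrix
  variants will differ.
- The RFE schedule (one feature per step, all subset sizes as candidates)
  is one reasonable reading; other schedules (halving, fixed subset
  grids) would select differently.
- The exact literature T2 anchors for fat and muscle at 3T are
  configuration values, not constants of nature; changing them rescales
  pseudo-T2 values affinely and leaves texture features unchanged.
- DeLong inference is asymptotic and breaks down at very small held-out
  sites: with only two or three tumors in a class the structural-component
  variance estimate collapses and the z-test can report absurdly small
  p-values for noise. Per-site DeLong comparisons are therefore only
  computed where both classes have at least five tumors at the test site
  (`augmentationTests(minPerClass = 5)`); the across-site paired t-test
  is the summary statistic in the small-site regime.
- The ANOVA screen assumes approximate log-normality of features; heavily
  skewed features with many nonpositive values rely on the positivity
  shift, which is a pragmatic, not principled, transform.
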