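---
title: "Methods: neuromelanin and iron MRI quantification in nigrascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuromelanin and iron MRI quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigrascan)
```

# The measurement problem

In Parkinson's disease, neuromelanin (NM)-containing dopaminergic neurons
of the substantia nigra (SN) and noradrenergic neurons of the locus
coeruleus (LC) degenerate. On magnetization-transfer-prepared
T1-weighted MRI these NM-rich nuclei appear hyperintense, so their volume
and contrast-to-noise ratio (CNR) act as in vivo proxies of neuronal
loss; iron-sensitive imaging (R2\*, magnetic susceptibility) probes the
accompanying iron load. nigrascan implements the measurement chains for
both windows plus the group-level statistics that relate them to striatal
dopamine-transporter (DAT) binding, and validates all of it on synthetic
phantoms with exact ground truth.

# Neuromelanin chain

## Model and procedure

For each analysed slice and side, a circular background ROI (diameter
4 mm, default) in the cerebral crus yields the reference mean `MN_CC` and
SD `SD_CC`. A voxel enters the binary map when its intensity is
*strictly greater than* `MN_CC + 3 * SD_CC`; the map is restricted to a
declared mesencephalic search region so distant hyperintensities cannot
leak in. Per slice and side the largest in-plane connected component is
kept (8-connectivity, so diagonal contact joins), components are stacked
over four consecutive slices, and

- volume = voxel count × voxel volume (mm³),
- `CNR_SN = (MN_SN − MN_CC) / SD_CC` per slice, averaged without
  area-weighting across the analysed slices.

The LC is too small for volumetry at a 0.5 × 0.5 × 3 mm grid, so only its
contrast is measured: `LC_MAX` is the highest-intensity voxel adjacent to
the fourth ventricle on each side, LC intensity is the mean of `LC_MAX`
and its four in-plane abutting voxels, and
`CNR_LC = (MN_LC − MN_TG) / SD_TG` against a 6 mm pontine-tegmentum ROI,
averaged over three consecutive slices. `%CNR` rescales a contrast to
percent of the healthy-control median so SN and LC become comparable, and
the asymmetry index `AI = |(ipsi − contra)/(ipsi + contra)| × 200` scores
left-right imbalance on a 0–200 scale (contralateral = opposite the
clinically worse hemibody; controls take the right side as ipsilateral).

Because the result depends on where a rater drops the reference ROIs, the
whole chain runs four times (default) with every reference-ROI centre
jittered by a uniform ±1-voxel in-plane shift, reporting the mean and
sample SD across repeats.

## Conventions and numerical choices

- **Indices** are 1-based voxel coordinates (the natural R convention);
  what matters is declared explicitly everywhere: a circle contains a
  voxel when the *voxel centre* lies within the radius, distances in mm.
- **Population vs sample SD.** `SD_CC`/`SD_TG` are population SDs
  (divisor n): the threshold is a statement about the reference-region
  voxel population. Repeat-averaging uses the sample SD (divisor n − 1):
  four repeats are a sample of rater behaviour.
- **Strict inequality** at the threshold: a voxel exactly at
  `MN + 3 SD` is excluded.
- **Slice window.** "The four consecutive slices in which the SN is
  visible" is operationalised as the 4-slice window maximising total
  suprathreshold component area; fewer non-empty slices are used with a
  warning, and a side with no suprathreshold cluster returns a flagged
  missing-side record rather than an error.
- **Ventricle adjacency** is a band of voxels within 2 in-plane voxels
  (Chebyshev distance) of the ventricle mask, excluding the mask,
  side-restricted; no adjacency radius is standard, and 2 voxels (1 mm)
  spans the LC cross-section at this resolution. Intensity ties in the
  band resolve to the smallest row, then column index.
- **Degenerate backgrounds.** A noise-free image has `SD_CC = 0`, which
  would make both the threshold trivial and the CNR undefined. The
  measurement driver then substitutes the configuration's declared
  `referenceSD` (the phantom's nominal background SD); the low-level
  `cnrSN()`/`cnrLC()` refuse a zero SD unless that reference is given.
- **Side split** is the volume's mid-sagittal plane; background
  statistics are kept per slice *and side* (the formula names the
  same-slice, same-side crus ROI), and the slice average of CNR is
  unweighted, following the plain reading of "average across slices".

# Iron chain

With exactly two echoes the log-linear least-squares solution of the
mono-exponential decay `S(TE) = S0 exp(−R2* TE)` has the closed form
`R2* = ln(S(TE1)/S(TE2)) / (TE2 − TE1)` (TE converted ms → s; R2\* in
1/s). The fit is exact on noise-free data, which the tests assert at
machine precision. Voxels with non-positive signal at either echo are
invalid; noise can push `S(TE2) ≥ S(TE1)`, giving an apparent negative
rate, which is clamped to zero and counted by default (tissue R2\* is
non-negative) or invalidated when `clamp = FALSE`.

SN ROI sampling is the unweighted mean over mask voxels per side,
excluding invalid voxels and reporting their fraction; masks spanning more
than six slices are reduced to the six consecutive slices with the largest
total area (the "six central slices" rule), and two repeats — emulated by
a one-voxel mask shift — are averaged arithmetically. Dipole inversion
itself (producing susceptibility maps from phase) is out of scope: the
pipeline consumes susceptibility maps as input and the generator produces
them directly.

# Cohort statistics

- **Mann-Whitney U**: exact two-sided p by enumeration of all group
  assignments when both groups have ≤ 8 subjects (ties handled by
  enumerating the observed mid-ranks); otherwise the tie-corrected normal
  approximation without continuity correction. The standard
  `wilcox.test` is the independent oracle in the tests, never the
  implementation.
- **Spearman batteries**: mid-rank ρ, p from the t approximation on
  n − 2 df, Benjamini-Hochberg adjustment across the user-declared
  battery (the correction family is an analysis choice, so it is an
  explicit argument), flags at adjusted p < 0.05. Constant variables
  yield a missing ρ rather than an error.
- **ROC**: candidate cut-offs are the midpoints between adjacent distinct
  values plus one candidate beyond each extreme; the AUC is the trapezoid
  area, which equals the rank statistic `U/(n1·n2)` (asserted on random
  tables). Orientation is declared per measure (`lower` ⇒ smaller values
  test positive), never inferred from the data. Three operating points
  are named: the cut-off keeping sensitivity at 100% with the best
  specificity, the cut-off keeping specificity at 100% with the best
  sensitivity, and the accuracy-maximising cut-off with ties broken by
  Youden's J and then the smaller cut-off — "best trade-off" has no
  canonical definition, so the package fixes one and documents it.
  Sensitivity/specificity intervals are exact Clopper-Pearson by beta
  quantile inversion. All-equal input degenerates to AUC 0.5 with a flag.
- **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement — the conservative form for averaging four single
  measurements by one rater; computed from the ANOVA mean squares and
  cross-checked against `aov` in the tests. Zero between-subject variance
  returns 0, flagged.
- **DAT prediction**: ordinary least squares with R², RMSE
  (`sqrt(SSE/df)`), PRESS from the hat matrix (equal to explicit
  leave-one-out refits, asserted to 1e-9), the overall F-test and
  per-predictor t-test p-values; the best predictor is the smallest
  per-predictor p. Collinearity is flagged as rank deficiency.

# The synthetic generator

`nmPhantom()` builds the minimal geometry that exercises every rule in the
chain: two SN ellipsoids spanning four slices whose voxel set is the
`round(V / voxelVolume)` voxels nearest the centre in normalised ellipsoid
distance (so the realised volume is exact to half a voxel and
`volume = count × voxelVolume` holds identically); single-voxel-wide LC
crosses (five voxels per slice) hugging a rectangular fourth ventricle
over three pontine slices; and signal-neutral crus/tegmentum cylinders
marking the reference-ROI sites. Structure intensity is
`bgMean + CNR × bgSD` plus additive Gaussian noise. Defaults: 96 × 96 × 12
voxels at 0.5 × 0.5 × 3.0 mm, background 100 ± 10, noise SD = background
SD. The LC cross centre is raised by `1e-9 × bgSD` purely to arbitrate
the arg-max in noise-free images; the perturbation is ~8 orders below any
reported precision.

The noise is Gaussian, not Rician: at the CNR regime of interest (≈ 3–5)
the Rician correction is negligible and the Gaussian keeps every oracle
analytic. The phantom deliberately omits B1 inhomogeneity, slice
cross-talk, magnetization-transfer physics and partial-volume blur beyond
voxelisation — so passing tests certify the *measurement chain*, not
robustness to scanner physics. Two consequences visible in the examples:
noisy threshold segmentation is conservative (edge voxels drop below
`MN + 3 SD`), and noisy CNR_LC is attenuated because with a
single-voxel-wide LC the localised maximum's neighbours are partly
background — both faithful behaviours of the method itself on a structure
at the resolution limit.

`dualEchoPhantom()`/`susceptibilityPhantom()` use two SN ellipsoids over
six slices on a 64 × 64 × 16, 1 mm grid, with mono-exponential decay from
`S0 = 1000` at TE 9.2/23 ms and region-constant ppm values respectively.

`simulateCohort()` draws each measure from its group's normal distribution
truncated at zero (all these quantities are physically non-negative;
at the default parameters the truncation is far in the tail and shifts
means negligibly). Within the PD group, contralateral SN volume and
contralateral putamen DAT binding are coupled by a Gaussian copula with
Pearson parameter `2 sin(π ρ / 6)`, hitting a target *Spearman* ρ exactly
in distribution — rank-based coupling because the downstream correlation
analysis is Spearman. The default target ρ is 0.75, consistent with a
reported least-squares R² of about 0.6 between SN volume and putaminal
binding. Asymmetry indices are derived from the drawn side pairs, so AI
margins are implied rather than imposed — the generator matches per-side
margins, and the AI distribution follows from them. Clinical covariates
are drawn from rounded normals matching the study population's summaries
(median age ≈ 63, disease duration ≈ 6 y, UPDRS-III ≈ 14); they are
plumbing for the correlation battery, not calibrated distributions.

Reproducibility contract: every generator takes a seed, restores the
caller's RNG state, and identical spec + seed gives bit-identical arrays.

# Problem sizes and tolerances

The test suite validates: exact recovery (volume to one voxel, CNR to
1e-9, R2\* to machine precision) on noise-free phantoms; sampling-error
bounds (4 standard errors) under noise; distributional properties by
Monte Carlo at fixed seeds — 10⁵-per-group cohort margins, 10⁴ draws for
the copula, 1000 repetitions for the LC arg-max uniformity χ² test, 500
replicate group comparisons at n = 18 + 18, 200 random tables for the
AUC–U identity; and oracle agreement for every statistic
(`wilcox.test`, `binom.test`, `aov`, explicit leave-one-out refits,
`p.adjust`). ROC operating characteristics are checked on 5000-per-group
cohorts, where the empirical AUC of the N(236, 50²) vs N(344, 51²)
contrast concentrates near the closed-form binormal value
Φ(108/√(50² + 51²)) ≈ 0.935, with sensitivity/specificity/accuracy at the
292 mm³ cut-off near 86.9 / 84.6 / 85.8%. These sizes keep the full suite
under a minute on one CPU while leaving every stochastic assertion
several standard errors of slack.

# Known limitations

- The phantom geometry is conventional, not anatomical: no atlas
  coordinates exist for it, and crus/tegmentum placement is chosen for
  clearance, not realism.
- Gaussian noise understates magnitude-image bias at very low SNR.
- LC volumetry is deliberately absent (unreliable at this resolution), as
  are nigral pars compacta/reticulata subdivision, atlas registration,
  QSM dipole inversion, and DICOM ingestion.
- Threshold segmentation under noise is biased low by construction; the
  package reports what the method measures, making the synthetic truth
  available for bias studies rather than correcting for it.
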