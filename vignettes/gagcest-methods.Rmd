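---
title: "Models and methods behind the gagcest pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the gagcest pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagcest)
library(dplyr)
```

## The measurement

Glycosaminoglycan chemical exchange saturation transfer (gagCEST) imaging
estimates the GAG content of cartilaginous tissue from the asymmetry of the
z-spectrum, the normalized saturation-weighted signal
$Z(\omega) = S_\mathrm{sat}(\omega) / S_0$ sampled at frequency offsets
$\omega$ around the water resonance. Saturation applied at the resonance of
GAG hydroxyl protons (about +1 ppm from water) is transferred to bulk water
by chemical exchange and depresses $Z$ on the positive side of the spectrum
only. The magnetization transfer ratio asymmetry

$$\mathrm{MTR_{asym}}(\Delta\omega) = Z(-\Delta\omega) - Z(+\Delta\omega)$$

averaged over the GAG-specific band $\Delta\omega \in [0.9, 1.9]$ ppm and
expressed in percent is the gagCEST effect size. In the lumbar spine it is
read out per intervertebral disk (IVD), whose GAG-rich nucleus pulposus (NP)
shows larger effects than the fibrous annulus fibrosus (AF), and it declines
with degeneration.

The package implements the full analysis chain for this observable —
simulation, B0 correction, mapping, disk segmentation, cohort statistics —
with simulated data standing in for patient acquisitions, which are not
publicly available for this kind of study. Every stage is therefore
validated against known synthetic ground truth rather than against scanner
data; what that does and does not demonstrate is discussed at the end.

## Forward model of the z-spectrum

`simulate_z_spectrum()` uses an analytic sum-of-Lorentzians saturation
profile:

$$Z(\omega) = 1 - L(\omega - \delta;\, A_w, \Gamma_w)
               - L(\omega - \delta - \omega_g;\, A_g, \Gamma_g)
               - L(\omega - \delta;\, A_m, \Gamma_m)$$

with a direct water-saturation pool, a GAG pool at $\omega_g \in
[0.9, 1.9]$ ppm (default 1.3 ppm, FWHM 0.8 ppm), an optional broad
symmetric magnetization-transfer pool, and the per-voxel B0 offset
$\delta$. A full Bloch–McConnell treatment would require the saturation
pulse amplitude and duration, which are not part of the acquisition
metadata this package consumes; the Lorentzian model reproduces the
observable of interest — a band-limited asymmetry whose magnitude scales
with the GAG pool amplitude — with an analytically known ground truth. The
mapping from amplitude to observable is exposed directly:
`pool_band_gagcest()` evaluates the closed-form band-averaged asymmetry for
any sampling scheme, and is what the phantom stores as per-pixel truth.

```{r forward-map}
offsets <- acquisition_spec()$cest_offsets
tibble::tibble(
  gag_amplitude = c(0.01, 0.02, 0.0323),
  band_gagcest_pct = sapply(
    gag_amplitude,
    function(a) pool_band_gagcest(pool_model(gag_amplitude = a), offsets)
  )
)
```

The relation is linear in the amplitude, so the phantom defaults
(`np_gag_amplitude = 0.0323`, `af_gag_amplitude = 0.0185`) place the NP and
AF ground truth at about 2.1 % and 1.2 % — the levels reported for healthy
NP and AF tissue.

Sampling defaults follow the acquisition they emulate: the z-spectrum sweep
reaches its stated maximum of ±3 ppm, and the water-reference (WASSR) sweep
±1 ppm. Point counts are not part of that specification; 33 and 21 evenly
spaced points were chosen once as typical of spine CEST protocols. Noise is
additive Gaussian on $Z$ (and on the S0 reference), the standard
high-SNR approximation to Rician magnitude noise; the default
`noise_sd = 0.01` of S0 corresponds to SNR 100 in the reference image.

## B0 correction by maximum symmetry

Field inhomogeneity shifts every voxel's spectrum by $\delta$ ppm, which
corrupts the asymmetry far more than it corrupts peak positions. The WASSR
acquisition — a narrow, direct-saturation-only sweep — locates the water
centre per voxel. `estimate_b0_voxel()` finds the candidate centre about
which the cubic-spline interpolant $\hat Z$ of the WASSR spectrum is most
mirror-symmetric, minimizing

$$C(\delta) = \sum_{w} \left[\hat Z(\delta + w) - \hat Z(\delta - w)\right]^2$$

over the sampled offset magnitudes $w$ whose reflected pairs both lie
inside the sweep (pairs that would need extrapolation are dropped rather
than extrapolated). Minimization is a coarse grid (step 0.01 ppm, half-width
0.5 ppm) followed by bounded scalar refinement, so the estimate is not
quantized to the grid. Spectra with too little dynamic range (minimum not
below 0.8 of the maximum) are flagged invalid instead of estimated —
this is what excludes background and keeps the map `NA`-free within its
validity mask. On noiseless simulated WASSR spectra the estimator is exact
to within 0.005 ppm; at `noise_sd = 0.02` its RMSE stays below 0.03 ppm,
both verified in the test suite.

`correct_spectrum()` then re-samples each CEST spectrum at its nominal
offsets after shifting the frequency axis, again with a cubic spline; the
one or two outermost offsets whose shifted positions leave the sweep are
filled from the nearest sample and flagged `extrapolated`. Band averaging in
`band_gagcest()` uses the nominal sampled offsets inside [0.9, 1.9] ppm
(with the default sweep: 0.9375, 1.125, 1.3125, 1.5, 1.6875, 1.875 ppm)
rather than a resampled grid, so the band content is an explicit function of
the sampling scheme. Map values are never clipped — negative gagCEST values
are physically possible under noise and asymmetric MT and are retained.

## The synthetic lumbar phantom

`phantom_scene()` builds a midsagittal geometry of six vertebral bodies and
five disks (L1/2–L5/S1), each disk an NP core (central 50 % of columns,
middle rows) inside an AF rim, over a smooth B0 field (default: a linear
craniocaudal ramp spanning ±0.3 ppm, a typical magnitude for lumbar-spine
shims at 3 T). `generate_phantom()` evaluates the forward model per pixel
and returns the stacks together with pixel-aligned truth: tissue labels,
disk levels, the NP mask, the B0 field, and the expected gagCEST map. The
phantom emulates the features the pipeline is sensitive to — band-limited
asymmetry, B0 shifts, tissue-dependent S0 and spectra, image noise — and
deliberately omits others: no partial-volume mixing at tissue borders, no
anatomical shape variation, no motion, no B1 inhomogeneity, no
reconstruction artefacts.

## Disk segmentation

Disk tissue is separated from bone and background by a Gaussian Bayes
classifier (`fit_bayes()` / `classify_pixels()`): class-conditional
multivariate normals with priors, over three default features per pixel —
normalized S0 intensity, mean normalized signal at weakly saturated offsets
(|ω| ≥ 2.5 ppm), and the normalized row coordinate. A pixel joins the disk
mask when its disk posterior exceeds 0.5. Zero-variance features are
ridge-regularized with a warning rather than rejected. In the pipeline the
classifier trains on a reference phantom generated with a separate internal
seed, so it never sees the evaluated noise realization.

Candidate disks are 4-connected components of the disk mask, filtered by
area (20–2000 px) and bounding-box elongation (≤ 8); exactly five must
survive, or `extract_disks()` raises an error listing the candidates — the
programmatic analogue of the visual confirmation step a radiologist would
apply when automatic identification fails. Survivors are labeled
L1/2–L5/S1 cranial to caudal by centroid row. The NP/AF partition rule
(central 50 % of each row's anteroposterior extent, left-biased centring
for odd widths) is a declared convention: published gagCEST spine studies
report NP/AF values without specifying their partition geometry, so the
fraction is a parameter with the phantom-truth overlap tests (Dice ≥ 0.7)
as its acceptance surface.

## Cohort statistics

The row unit of the statistical models is one disk-region observation
joined to subject covariates. `fit_cohort_lmm()` fits, by restricted
maximum likelihood via `lme4`,

$$y_{ij} = \mu + X_{ij}\beta + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad \varepsilon_{ij} \sim N(0, \sigma^2)$$

with a subject-specific random intercept $b_i$ and fixed effects for the
factor of interest (cohort), segment, their interaction, region when
per-region rows are present, mean-centred age, gender, and the dichotomized
Pfirrmann grade (1–2 non-degenerated vs 3–5 degenerated). The adjacency
model replaces cohort with the adjacency class (extruded / adjacent /
non-adjacent, defined by sharing a vertebra with the extruded segment) and
contains no segment term, mirroring its reported specification — segment is
near-collinear with adjacency because extrusions occur only at L4/5 and
L5/S1, and including it substantially inflates the variance of the
extruded-class estimate.

`marginal_means()` reports estimated marginal means per stratum, averaging
over the *observed* distribution of the other factors (proportional
weights, covariates at their means) rather than a balanced reference grid —
with near-balanced cohorts the two estimands differ negligibly, and the
observed-distribution choice keeps single-factor balanced designs exactly
equal to raw stratum means. Intervals default to 99 % and use the normal
approximation on the fixed-effect covariance (`df = Inf` in the output
flags this); with 54 subjects the difference from a
degrees-of-freedom-corrected interval is well below the reporting
precision. Estimates and intervals lead the output; p-values are not
emphasized anywhere in the reporting functions. Pfirrmann grades are
compared across cohorts by the tie-corrected Kruskal–Wallis test, with
Dunn's rank-based pairwise z statistics (Bonferroni-adjusted; no adjustment
method is standard here, and Bonferroni is the most conservative
convention) computed only when the omnibus test rejects at 0.05.

## Calibration of the packaged scenarios

Each packaged scenario fixes its ground-truth means to one reported
stratification, so replicate-averaged recovery can be compared with those
values:

```{r truths}
list(
  cohort = scenario_truth(scenario_cohort()),
  region = scenario_truth(scenario_region()),
  degeneration = scenario_truth(scenario_degeneration()),
  adjacency = scenario_truth(scenario_adjacency())
)
```

Two calibration choices deserve justification. First, the reported
segment-level cohort cells are covariate-adjusted and do not average
exactly to the reported cohort overalls (the nsLBP cells average 1.4
against an overall of 1.3); `scenario_cohort()` recentres each cohort's
segment profile by a constant so the balanced segment average equals the
overall, keeping the headline cohort contrast exact while preserving the
segment pattern. Second, the reported per-cohort Pfirrmann grade counts are
internally inconsistent with the cohort sizes; the scenarios use the count
*proportions*, whose implied mean grades (2.7 / 2.6 / 2.3) match the
reported per-cohort means. A single scenario jointly consistent with every
reported stratification cannot exist, because the covariate-adjusted strata
are not mutually consistent — hence four separate scenarios.

The variance components default to $\sigma_b = 0.5$ % and $\sigma = 0.8$ %.
These are not reported quantities; they were chosen once as plausible given
the widths of the printed 99 % confidence intervals (about ±0.3 % on cohort
means of 80–100 disks, which back-solves to a total SD near 1 %), and both
are scenario parameters. Ages are drawn uniformly over each cohort's
reported range and genders follow the reported counts; neither enters the
response, so they act purely as confounders the models must absorb.
Radiculopathy subjects receive exactly one extrusion each, nine at L4/5 and
nine at L5/S1, as reported.

## Numerical conventions and degenerate inputs

* Interpolation is everywhere a natural cubic spline on the sampled points;
  no extrapolation is performed anywhere — reflected pairs outside the
  WASSR sweep are dropped from the symmetry cost, and shifted CEST offsets
  outside the sweep reuse the nearest sample and are flagged.
* Pixel coordinates are 1-based (row, col) in R convention, row-major,
  craniocaudal = increasing row; stacks are `H x W x n_offsets`.
* Simulated `Z` is clipped to [0, 1]; computed MTRasym maps are not
  clipped.
* Flat spectra, empty ROI partitions, and missing strata are flagged
  (`NA` / `valid = FALSE` / `partition_ok = FALSE`), never silently zeroed;
  singular mixed-model fits warn and return, rank-deficient designs error
  naming the aliased terms.
* All generators take a seed and are bit-reproducible; pipeline reruns with
  the same configuration produce byte-identical tables.

## Problem sizes used by the packaged checks

The phantom is 120 × 48 pixels (about 2300 foreground pixels, 600 disk
pixels), which resolves five disks with realistic relative geometry while
keeping a full pipeline run at a few seconds. Statistical recovery uses 25
replicates per scenario of the full cohort design (54 subjects × 5
segments, or 18 × 5 for adjacency); across-replicate SDs of the recovered
marginal means are about 0.1–0.25 %, so 25-replicate averages resolve the
printed values to better than ±0.15–0.2 %. The B0 noise study uses 100
seeds and the Kruskal–Wallis null calibration 1000.

## Limitations

Passing phantom tests demonstrates correctness of the processing chain
under the forward model's assumptions, not clinical validity: real spectra
deviate from Lorentzian line shapes, real B0 fields are not separable from
motion and susceptibility effects, and real disk boundaries are not
piecewise-rectangular. The statistics-level scenarios inherit the printed
stratum means as truth; recovery shows the estimation pipeline is unbiased
and appropriately calibrated for data *generated under the stated model*,
not that the model is the true data-generating process of patient spines.
The package deliberately implements no Pfirrmann grading from images, no
extrusion detection, and no alternatives to MTRasym (Lorentzian-difference
fitting, T2* or T1rho mapping are out of scope).
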