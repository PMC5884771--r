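---
title: "Semiquantitative autofluorescence profiling: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiquantitative autofluorescence profiling: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiqaf)
```

## The problem

Congenital achromatopsia (ACHM) is a cone dysfunction syndrome: absent or
severely reduced cone function with preserved rods, presenting with low
acuity, photophobia, nystagmus and color vision deficiency. Fundus
autofluorescence (AF) imaging captures metabolic signatures of the retinal
pigment epithelium — lipofuscin on short-wavelength excitation (SW-AF),
melanin compounds on near-infrared excitation (NIR-AF) — and both
modalities show characteristic foveal lesions in ACHM: a perifoveal
hyperautofluorescent ring on SW-AF and, in more advanced disease, a central
hypoautofluorescent area inside the normally hyperautofluorescent macular
center on NIR-AF.

Reading these lesions directly off images is hard in ACHM because
photophobia and nystagmus degrade image quality. The semiquantitative
approach implemented here converts each image into a one-dimensional radial
profile that averages out fixation artifacts: mean gray level along nasal
and temporal semicircles centered on the fovea, normalized against two
intra-image references, compared pointwise with a healthy-control envelope.

## The profile model

For each integer radius $r = 1 \dots R$ (pixels) the mean 8-bit gray level
$AF_{measured}(r)$ is taken along the nasal and the temporal semicircle
centered on the fovea. Two reference intensities are extracted from the
same image: $AF_{ref}$, the mean over a circular region on the optic nerve
head (physiologically devoid of autofluorescence, so it acts as the zero
point), and $AF_{mean}$, the mean over the full image. The normalized
profile is

$$AF(r) = \frac{AF_{measured}(r) - AF_{ref}}{AF_{mean} - AF_{ref}}$$

so $AF = 0$ at the reference and $AF = 1$ at the image-average level. The
normalization is invariant under any gain/offset applied to all pixels —
the property that makes profiles comparable across acquisitions with
different amplifier settings — and this invariance is verified to machine
precision in the test suite.

Radii convert to visual degrees by a per-image scale (default
$30^\circ/768\,\mathrm{px} \approx 0.039^\circ$/px, the standard 30-degree
confocal field), and profiles are resampled by linear interpolation onto a
fixed 0.05-degree grid so that profiles and control bands share a common
axis.

Design choices made where the procedure was genuinely open:

* **Circle sampling.** Semicircles are sampled by bilinear interpolation at
  angular steps of arc length at most 1 px, rather than by collecting
  pixels whose rounded distance equals $r$. The two agree within half a
  gray level on smooth fields at full acquisition scale (oracle-tested);
  interpolated sampling behaves better at small radii where integer-radius
  annuli are sparse and anisotropic.
* **Hemifield assignment and ties.** The vertical meridian through the
  fovea splits the hemifields; the half containing the optic disc is
  nasal. Samples are placed at angular midpoints so none falls exactly on
  the meridian (a measure-zero tie, excluded from both hemifields).
* **Radius limit.** $R = \lfloor\min(\text{distance fovea–disc center},
  \text{distance fovea–nearest border})\rfloor$: no circle leaves the
  image and none reaches the disc center. With typical landmarks this
  yields the familiar 160–200 px range.
* **Reference ROI.** $AF_{ref}$ averages a disc-centered circular ROI
  (default radius 15 px) rather than a single manually picked pixel; the
  radius is configurable. Disc pixels are *not* masked out of $AF_{mean}$
  (configurability was considered and rejected: no masking rule exists in
  routine practice, and the affine invariance makes the choice a second-
  order effect).
* **Degenerate input.** A constant image has $AF_{mean} = AF_{ref}$ and no
  defined profile; this raises an error rather than returning infinities.

## The control envelope

Profiles from healthy control eyes (eight, in the clinical design this
package follows) are averaged across their two hemifields, then a
pointwise mean and sample standard deviation (n−1) are taken over the
common eccentricity grid. The mean ± SD band is the reference envelope:
patient curves are plotted against it and lesion calls are made relative
to it.

## Lesion metrics

The clinical study this package operationalizes measured lesion diameters
manually on the plots; the automatic rules below are this package's own
definitions, chosen so that noiseless phantom truth is recovered exactly,
and every threshold is an exposed argument.

* **SW-AF perifoveal ring** (`detect_ring`). The profile is smoothed by a
  0.25° moving average. A ring is present when *both* hemifields show a
  contiguous span of at least 0.25°, within 0.3–8° eccentricity, where the
  smoothed profile exceeds band mean + 1 SD. The diameter is peak-to-peak:
  the sum of the two hemifields' maximal-excess eccentricities. (Whether
  the original manual measurements were peak-to-peak or edge-to-edge is
  not documented; peak-to-peak is used because the peak of a ridge is
  better defined than its edge on noisy curves.) The search additionally
  stops 2.6° short of the optic-disc center: once nasal semicircles touch
  the disc, the hemifield-averaged band is no longer a valid reference for
  either hemifield.
* **NIR-AF central hypoautofluorescence** (`detect_central_hypoaf`).
  Present when both hemifields dip below band mean − 1 SD within the
  central 3°; the diameter sums, over hemifields, the eccentricity where
  the smoothed curve re-crosses that lower edge from below (with linear
  interpolation between grid points). A *borderline* call — the
  ill-defined central decrease that cannot be assigned to either group —
  requires both hemifields to dip below mean − 0.5 SD without reaching
  mean − 1 SD. The half-SD margin is needed because any noisy curve falls
  marginally below the band mean somewhere; without it, essentially every
  normal eye would be called borderline.
* **Two observers** (`average_observers`) average their diameters
  arithmetically only when their categorical calls agree; disagreement is
  surfaced as an error, never silently resolved.

## Synthetic phantoms

Raw clinical images for this disease are not publicly deposited, so
pipeline validation uses a ground-truthed phantom generator
(`phantom_spec`/`gen_af_phantom`). The noiseless image is radially
symmetric about the fovea:

* baseline gray level, default 120;
* modality-dependent central term: SW, a Gaussian foveal depression
  (depth 60, SD 1°); NIR, a Gaussian central macular peak (amplitude 60,
  SD 2°);
* optional perifoveal ring: Gaussian bump in eccentricity (amplitude 30,
  SD 0.35°) at the ring eccentricity;
* optional central hypoautofluorescent core: logistic-edged plateau
  (depth 70, edge softness 0.05°) of the given half-width.

Lesion cross-sections are smooth by design — the source imagery shows but
does not parameterize them, and smooth models make crossing-based
diameters well defined. The optic disc is rendered as a near-zero filled
circle (the reference region is physiologically dark, which puts
$AF_{ref}$ at the image minimum and the disc at the plots' zero line). A
radial vignette (strength 0.1), horizontal box blur (emulating the purely
horizontal fixation jitter of nystagmus; no quantitative nystagmus model
is attempted), additive Gaussian noise (SD 2 gray levels) and 8-bit
quantization complete the forward model. Everything is deterministic given
the `phantom_spec` seed.

**Ground truth.** The ring diameter is exactly `2 * ring_ecc` (the bump
peaks there by construction). The core diameter is defined by applying the
same crossing rule the detector uses to the *noiseless, unblurred* phantom
against its lesion-free counterpart, with a nominal band SD of 0.025
normalized units — the envelope spread the default control panel actually
produces (measured 0.018–0.03 across seeds). Because the plateau edge is
steep (0.05° logistic scale), the crossing point moves only ~0.035° per
factor-of-two error in that nominal SD, which keeps truth and measurement
consistent well within the ±0.2° recovery tolerance.

**Control panels** (`gen_control_phantoms`) perturb baseline (SD 4 gray
levels), the central term's amplitude and width (5% each) and the vignette
strength (SD 0.03) across eyes. The vignette perturbation matters: pure
gray-level offsets are normalized away by design, so without some
far-field anatomical variability the control envelope would collapse to
the noise floor at high eccentricity and any fluctuation would spuriously
exceed it.

**Cohort simulation** (`gen_cohort`) reproduces the statistical structure
the cohort analyses assume: the probability of a NIR-AF core is logistic
in age (50% at 23 years, scale 5 years — bracketing the observed group
means of ~31.5 vs ~15.5 years), the core half-width grows linearly with
age among affected patients (default 0.03°/year plus 0.08° noise), and
the OCT ellipsoid-zone defect width tracks the core diameter
(unit slope, 0.15° noise). Simulated cohorts default to compact 256-px
images, which run the full image-to-statistics pipeline for 60 patients in
a few seconds.

What the phantoms deliberately do *not* model: optics/PSF realism,
fluorophore physiology, asymmetric or non-circular lesions, eye-motion
artifacts beyond horizontal blur, and OCT B-scans (the ISe width is
generated directly as a number). Passing the recovery tests therefore
demonstrates correctness of the measurement chain under the stated image
model, not robustness to every real-world artifact.

## Statistics

The cohort statistics mirror small-sample clinical practice:

* `mann_whitney_exact` — U from midranks; p by complete enumeration of all
  group assignments of the pooled values (ties handled exactly), refused
  above 20 total observations rather than silently approximated.
  Two-sided p is twice the smaller tail, capped at 1.
* `fisher_exact` — hypergeometric; one-sided is the tail in the observed
  direction, two-sided sums all tables no more probable than the observed
  one. The group-comparison wrapper (`nir_group_analysis`) defaults to
  one-sided for the stage-by-NIR-group table, with two-sided exposed.
* `wilcoxon_paired` — signed ranks with zeros dropped; exact by sign-flip
  enumeration up to n = 15, tie-corrected normal approximation beyond.
* `spearman_cor` — Pearson correlation of midranks; two-sided p by the
  t approximation (exact permutation with ties is impractical at n = 16),
  with a Monte-Carlo permutation option.
* `icc_agreement` — inter-observer: two-way, absolute-agreement,
  single-measures ICC with the standard F-based 95% CI; intra-observer:
  one-way random ICC. The agreement band is read from the *lower* CI
  bound: poor < 0.50 ≤ moderate < 0.75 ≤ good ≤ 0.90 < excellent (the
  0.75–0.90 band is called "substantial" in some nomenclatures).
* No multiple-testing correction anywhere: raw p-values against 0.05, as
  is conventional for exploratory cohort description.

All exact tests are verified against independent brute-force oracles
(pairwise-U enumeration, bitmask sign enumeration, exhaustive
hypergeometric summation) on all small inputs, and the exact Mann-Whitney
test's type-I error is checked against its *attainable* level — the
rejection probability of a discrete test at nominal 0.05 is below 0.05 by
construction, and calibration is judged against that attainable value.

## Numerical choices and degenerate inputs

* Eccentricity grid step 0.05°; smoothing window 0.25° (5 grid points).
* Grid points inside the innermost sampled radius take the innermost
  value (constant extrapolation); beyond data, bands and profiles error
  rather than extrapolate.
* Re-crossing eccentricities are linearly interpolated between grid
  points; a profile that never re-crosses the envelope reports its maximal
  eccentricity.
* Constant images, empty contingency margins, all-zero paired
  differences, zero between-subject variance and sub-minimal sample sizes
  all raise informative errors instead of producing NaN.
* Simulation problem sizes used by the validation suite: 20 seeds for
  lesion-diameter recovery, 60-patient imaging cohorts for association
  recovery, 1000 truth-level null cohorts for false-positive calibration
  (binomial precision at 1000 replicates is ±1.4 percentage points,
  tight enough to distinguish 5% from meaningful miscalibration).

## Known limitations

* Landmarks (fovea, disc) are inputs; no automatic detection is provided,
  matching the visual-identification step of the clinical procedure.
* The semicircular averaging folds superior and inferior retina into the
  nasal/temporal curves, diluting any vertical asymmetry — inherent to
  the method, not recoverable downstream.
* The packaged 16-patient table reproduces the published per-patient
  variables; the underlying two-observer raw measurements and per-patient
  lesion diameters were never published, so observer-agreement machinery
  is validated by construction and simulation, not against the published
  agreement table.
* Borderline NIR-AF calls depend on the 0.5-SD margin; the margin is a
  package definition (exposed as `borderline_mult`), not a published
  clinical threshold.
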