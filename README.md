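# semiqaf

Semiquantitative fundus autofluorescence (AF) profiling for congenital
achromatopsia (ACHM) and related cone dysfunction syndromes.

ACHM eyes show two characteristic foveal AF lesions: a perifoveal
hyperautofluorescent ring on short-wavelength AF (SW-AF) and, in more
advanced disease, a central hypoautofluorescent area inside the normally
bright macular center on near-infrared AF (NIR-AF). Because photophobia and
nystagmus degrade ACHM image quality, these lesions are best read from
*semiquantitative radial profiles* rather than raw images. `semiqaf`
implements that pipeline end to end for clinicians and imaging researchers:

1. **Radial profiling** — mean gray level along nasal and temporal
   semicircles of radius 1..R pixels centered on the fovea, normalized as

   `AF(r) = (AF_measured(r) − AF_ref) / (AF_mean − AF_ref)`

   with `AF_ref` the mean over an optic-nerve-head region (physiologic zero)
   and `AF_mean` the full-image mean, then converted to degrees of visual
   angle and resampled onto a 0.05° grid. The normalization is invariant to
   gray-level gain/offset.
2. **Control envelope** — pointwise mean ± SD band over hemifield-averaged
   profiles from healthy control eyes.
3. **Lesion metrics** — presence/borderline calls and diameters in degrees
   for the SW-AF ring (peak-to-peak over the band's upper edge) and the
   NIR-AF central hypoautofluorescence (re-crossing of the band's lower
   edge), plus two-observer averaging with explicit disagreement handling.
4. **Synthetic phantoms** — a ground-truthed generator for SW/NIR fundus
   phantoms (foveal dip/peak, ring, hypoAF core, optic disc, vignette,
   nystagmus-like blur, noise) and whole simulated cohorts with
   age-dependent disease structure, used to validate the pipeline since raw
   clinical images of this rarity are not publicly deposited.
5. **Cohort statistics** — exact enumeration-based Mann–Whitney and paired
   Wilcoxon tests, Fisher's exact test, tie-aware Spearman correlation, and
   intraclass correlation with CI-based agreement bands; plus a packaged
   16-patient ACHM cohort table (`fixture_table2()`).

## Worked example

Measure the NIR-AF central hypoautofluorescence of a synthetic patient eye
against a simulated 8-eye control panel:

```r
library(semiqaf)

geometry <- list(width = 256, height = 256, scale = 30/256,
                 fovea = c(128, 128), disc_center = c(208, 128),
                 disc_radius = 20)

patient <- gen_af_phantom(do.call(phantom_spec, c(geometry, list(
  modality = "NIR", hypo_core_ecc = 0.8, blur_len = 3, seed = 42))))

controls <- gen_control_phantoms(
  8, base_spec = do.call(phantom_spec, c(geometry, list(modality = "NIR"))),
  seed = 3)
band <- build_control_band(lapply(controls, semiquant_profile))

profile <- semiquant_profile(patient$image)
profile
#> <af_profile 'phantom-NIR-seed42'> NIR OD, eccentricity 0.05-9.35 deg (187 points)

detect_central_hypoaf(profile, band)
#> $status
#> [1] "present"
#> $diameter_deg
#> [1] 2.113969
```

The detected diameter (2.11°) recovers the phantom's ground truth (1.97°,
defined by the same crossing rule on the noiseless image) within the
pipeline's validated ±0.2° tolerance. A lesion with a 0.8° core half-width
is called "present" because both hemifields dip below the control band's
lower edge.

The packaged cohort reproduces the published headline statistics:

```r
cohort_report()
#> Cohort report (n = 16)
#>   mean age: 25.1 +/- 11.5 years
#>   SW-AF perifoveal ring: 12/16; NIR-AF central hypoAF: 7 (+2 borderline)
#>   foveal hypoplasia: 8; OCT stages 1-4: 4/5/3/4
#>   CNGA3 refraction: 50% myopia / 50% hyperopia
#>   CNGB3 refraction: 86% myopia / 14% hyperopia
#>   Spearman BCVA OD vs OS (LogMAR): rho = 0.82, p = 0.00011
#> NIR-AF central hypoautofluorescence group comparison
#>   age, present group: 31.4 +/- 9.3 years (n=7)
#>   age, normal group:  15.6 +/- 6.7 years (n=7)
#>   exact Mann-Whitney two-sided p = 0.004
#>                    stage 3-4 stage 1-2
#> NIR hypoAF present         5         2
#> NIR hypoAF absent          1         6
#>   Fisher one.sided p = 0.051 (2 borderline case(s) excluded)
```

Patients with a central NIR-AF hypoautofluorescent area are twice as old as
those without (exact Mann–Whitney p = 0.004) and more often show advanced
outer-retinal alteration on OCT (stage 3–4; one-sided Fisher p = 0.051) —
the age-dependence that motivates NIR-AF as a progression biomarker.

A command-line front end (`inst/cli/afq.R`) exposes the same pipeline as
`profile`, `band`, `measure`, `simulate`, `cohort-stats` and `report`
subcommands; the combined SW/NIR plot with control band and striped
ISe-defect overlay is rendered by `render_combined_plot()`.

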