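#' Specification of a synthetic autofluorescence phantom
#'
#' Describes one synthetic fundus-autofluorescence acquisition. The
#' noiseless image model is radially symmetric about the fovea:
#'
#' \deqn{I_0(e) = baseline + center(e) + ring(e) + core(e)}
#'
#' where `e` is eccentricity in degrees, `center` is a Gaussian foveal term
#' (a central depression of depth `fovea_dip_depth` for SW, a central
#' macular peak of amplitude `peak_amp` for NIR), `ring` is a Gaussian bump
#' of amplitude `ring_amp` centered at `ring_ecc` with SD `ring_width`
#' (the perifoveal hyperautofluorescent ring), and `core` is a
#' logistic-edged plateau of depth `hypo_core_depth` and half-width
#' `hypo_core_ecc` (the NIR central hypoautofluorescent area). The optic
#' disc is rendered as a near-zero filled circle, a radial vignette and
#' horizontal box blur (nystagmus-like fixation artifact) are applied, and
#' Gaussian noise is added before 8-bit quantization.
#'
#' @param width,height image size in pixels.
#' @param scale degrees per pixel.
#' @param fovea,disc_center 0-based `(x, y)` landmark coordinates.
#' @param disc_radius radius of the rendered disc, pixels.
#' @param modality `"SW"` or `"NIR"`.
#' @param laterality `"OD"` or `"OS"`.
#' @param baseline background gray level.
#' @param fovea_dip_depth,fovea_dip_sigma SW central depression: depth
#'   (gray levels) and Gaussian SD (degrees).
#' @param peak_amp,peak_sigma NIR central macular peak: amplitude (gray
#'   levels) and Gaussian SD (degrees).
#' @param ring_ecc ring-center eccentricity in degrees, or `NULL` for no
#'   ring.
#' @param ring_width,ring_amp ring Gaussian SD (degrees) and amplitude
#'   (gray levels).
#' @param hypo_core_ecc hypoautofluorescent-core half-width in degrees, or
#'   `NULL` for no core.
#' @param hypo_core_depth core depth in gray levels.
#' @param hypo_core_edge logistic edge softness of the core, degrees.
#' @param disc_level gray level of the rendered disc.
#' @param vignette_strength 0..1 quadratic intensity falloff towards the
#'   image corners.
#' @param noise_sigma additive Gaussian noise SD, gray levels.
#' @param blur_len horizontal box-blur length in pixels (0 or 1 = none).
#' @param seed integer seed making the phantom deterministic.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(width = 768, height = 768, scale = 30 / 768,
                         fovea = c(384, 384), disc_center = c(584, 384),
                         disc_radius = 50,
                         modality = c("SW", "NIR"),
                         laterality = c("OD", "OS"),
                         baseline = 120,
                         fovea_dip_depth = 60, fovea_dip_sigma = 1.0,
                         peak_amp = 60, peak_sigma = 2.0,
                         ring_ecc = NULL, ring_width = 0.35, ring_amp = 30,
                         hypo_core_ecc = NULL, hypo_core_depth = 70,
                         hypo_core_edge = 0.05,
                         disc_level = 2, vignette_strength = 0.1,
                         noise_sigma = 2, blur_len = 0, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               scale = scale, fovea = as.numeric(fovea),
               disc_center = as.numeric(disc_center),
               disc_radius = disc_radius,
               modality = match.arg(modality),
               laterality = match.arg(laterality),
               baseline = baseline,
               fovea_dip_depth = fovea_dip_depth,
               fovea_dip_sigma = fovea_dip_sigma,
               peak_amp = peak_amp, peak_sigma = peak_sigma,
               ring_ecc = ring_ecc, ring_width = ring_width,
               ring_amp = ring_amp,
               hypo_core_ecc = hypo_core_ecc,
               hypo_core_depth = hypo_core_depth,
               hypo_core_edge = hypo_core_edge,
               disc_level = disc_level,
               vignette_strength = vignette_strength,
               noise_sigma = noise_sigma, blur_len = as.integer(blur_len),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$scale <= 0 || spec$width < 16 || spec$height < 16)
    stop("invalid phantom geometry")
  if (spec$vignette_strength < 0 || spec$vignette_strength > 1)
    stop("vignette_strength must be in [0, 1]")
  if (spec$noise_sigma < 0 || spec$blur_len < 0)
    stop("noise_sigma and blur_len must be non-negative")
  border_deg <- min(spec$fovea[1], spec$fovea[2],
                    (spec$width - 1) - spec$fovea[1],
                    (spec$height - 1) - spec$fovea[2]) * spec$scale
  for (e in c(spec$ring_ecc, spec$hypo_core_ecc))
    if (e <= 0 || e >= border_deg)
      stop("lesion eccentricities must lie strictly between 0 and the ",
           "fovea-to-border distance (", round(border_deg, 2), " deg)")
  lo <- spec$baseline -
    (if (spec$modality == "SW") spec$fovea_dip_depth else 0) -
    (if (!is.null(spec$hypo_core_ecc)) spec$hypo_core_depth else 0)
  hi <- spec$baseline +
    (if (spec$modality == "NIR") spec$peak_amp else 0) +
    (if (!is.null(spec$ring_ecc)) spec$ring_amp else 0)
  if (lo < 0 || hi > 255)
    stop("gray-level parameters leave the noiseless range [0, 255]")
  invisible(spec)
}

# Noiseless analytic radial model of a spec, before vignette/disc/clip.
phantom_radial_model <- function(spec, ecc_deg) {
  v <- rep(spec$baseline, length(ecc_deg))
  if (spec$modality == "SW") {
    v <- v - spec$fovea_dip_depth *
      exp(-ecc_deg^2 / (2 * spec$fovea_dip_sigma^2))
  } else {
    v <- v + spec$peak_amp * exp(-ecc_deg^2 / (2 * spec$peak_sigma^2))
  }
  if (!is.null(spec$ring_ecc) && spec$ring_amp != 0)
    v <- v + spec$ring_amp *
      exp(-(ecc_deg - spec$ring_ecc)^2 / (2 * spec$ring_width^2))
  if (!is.null(spec$hypo_core_ecc) && spec$hypo_core_depth != 0)
    v <- v - spec$hypo_core_depth *
      stats::plogis((spec$hypo_core_ecc - ecc_deg) / spec$hypo_core_edge)
  v
}

# Render the noiseless, unblurred image of a spec (vignette + disc + clip).
render_noiseless <- function(spec) {
  x <- 0:(spec$width - 1); y <- 0:(spec$height - 1)
  ecc_px <- sqrt(outer((y - spec$fovea[2])^2, (x - spec$fovea[1])^2, "+"))
  img <- matrix(phantom_radial_model(spec, as.vector(ecc_px) * spec$scale),
                nrow = spec$height)
  if (spec$vignette_strength > 0) {
    cx <- (spec$width - 1) / 2; cy <- (spec$height - 1) / 2
    r2 <- outer((y - cy)^2, (x - cx)^2, "+") / (cx^2 + cy^2)
    img <- img * (1 - spec$vignette_strength * r2)
  }
  disc <- sqrt(outer((y - spec$disc_center[2])^2,
                     (x - spec$disc_center[1])^2, "+")) <= spec$disc_radius
  img[disc] <- spec$disc_level
  pmin(pmax(img, 0), 255)
}

# Horizontal box blur with edge replication.
box_blur_rows <- function(img, len) {
  if (len <= 1L) return(img)
  half_l <- (len - 1L) %/% 2L
  half_r <- len - 1L - half_l
  w <- ncol(img)
  idx <- outer(seq_len(w), (-half_l):half_r, "+")
  idx[idx < 1L] <- 1L; idx[idx > w] <- w
  out <- img
  for (i in seq_len(nrow(img)))
    out[i, ] <- rowMeans(matrix(img[i, ][idx], nrow = w))
  out
}

# Exact azimuthal mean by integer-radius per-pixel binning (used for truth
# and as an independent oracle in tests).
bin_radial_means <- function(pixels, fovea, R) {
  x <- 0:(ncol(pixels) - 1); y <- 0:(nrow(pixels) - 1)
  r <- round(sqrt(outer((y - fovea[2])^2, (x - fovea[1])^2, "+")))
  keep <- r >= 1 & r <= R
  means <- tapply(pixels[keep], r[keep], mean)
  out <- rep(NA_real_, R)
  out[as.integer(names(means))] <- means
  out
}

# Apply the central-hypoAF crossing rule to noiseless lesion vs lesion-free
# phantoms: normalized binned profiles, threshold = lesion-free profile
# minus band_sd; diameter = 2 x eccentricity where the lesion profile
# re-crosses the threshold from below (linear interpolation between radii).
truth_hypo_diameter <- function(spec, band_sd) {
  if (is.null(spec$hypo_core_ecc) || spec$hypo_core_depth == 0) return(0)
  base_spec <- spec
  base_spec$hypo_core_ecc <- NULL
  img_l <- render_noiseless(spec)
  img_b <- render_noiseless(base_spec)
  R <- floor(min(sqrt(sum((spec$fovea - spec$disc_center)^2)),
                 spec$fovea[1], spec$fovea[2],
                 (spec$width - 1) - spec$fovea[1],
                 (spec$height - 1) - spec$fovea[2]))
  norm_prof <- function(img) {
    m <- bin_radial_means(img, spec$fovea, R)
    ref <- spec$disc_level
    (m - ref) / (mean(img) - ref)
  }
  d <- norm_prof(img_l) - (norm_prof(img_b) - band_sd)   # below threshold iff < 0
  ecc <- seq_len(R) * spec$scale
  below <- which(d < 0)
  if (!length(below)) return(0)
  i <- below[1]
  j <- which(d >= 0 & seq_along(d) > i)
  if (!length(j)) return(2 * max(ecc))
  j <- j[1]
  frac <- -d[j - 1] / (d[j] - d[j - 1])
  2 * (ecc[j - 1] + frac * (ecc[j] - ecc[j - 1]))
}

#' Generate a synthetic autofluorescence phantom with ground truth
#'
#' Renders the noiseless radial model of `spec` (see [phantom_spec()]),
#' applies vignette, optic disc, horizontal box blur and additive Gaussian
#' noise, and quantizes to 8-bit. Deterministic for a fixed `spec$seed`.
#'
#' The returned truth records the nominal ring diameter (`2 * ring_ecc`)
#' and the hypoautofluorescent-core diameter obtained by applying the
#' lesion-metrics crossing rule to the noiseless image against its
#' lesion-free counterpart with a nominal band SD (`truth_band_sd`,
#' normalized units; the default matches the envelope spread the default
#' [gen_control_phantoms()] panel produces).
#'
#' @param spec a [phantom_spec()].
#' @param truth_band_sd nominal control-band SD used for the truth crossing
#'   rule.
#' @return list with elements `image` (an [af_image()]) and `truth` (list
#'   `ring_diameter_deg`, `hypo_diameter_deg`, `spec`).
#' @export
gen_af_phantom <- function(spec, truth_band_sd = 0.025) {
  validate_phantom_spec(spec)
  img <- render_noiseless(spec)
  img <- box_blur_rows(img, spec$blur_len)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                        nrow = nrow(img))
  img <- round(pmin(pmax(img, 0), 255))
  image <- af_image(img, modality = spec$modality,
                    laterality = spec$laterality, scale = spec$scale,
                    fovea = spec$fovea, disc_center = spec$disc_center,
                    disc_radius_px = min(15, spec$disc_radius),
                    id = sprintf("phantom-%s-seed%d", spec$modality, spec$seed))
  truth <- list(
    ring_diameter_deg = if (!is.null(spec$ring_ecc) && spec$ring_amp != 0)
      2 * spec$ring_ecc else 0,
    hypo_diameter_deg = truth_hypo_diameter(spec, truth_band_sd),
    spec = spec)
  list(image = image, truth = truth)
}

#' Generate lesion-free control phantoms
#'
#' Produces `n` lesion-free phantoms from `base_spec` (ring and core
#' removed) with small random perturbations of the baseline and of the
#' central dip/peak parameters, emulating a panel of healthy control eyes.
#' When every perturbation scale is zero the same spec (including its seed)
#' is rendered `n` times, so the images are identical.
#'
#' @param n number of controls (>= 2; the downstream control band needs a
#'   standard deviation).
#' @param base_spec a [phantom_spec()]; its ring/core parameters are
#'   ignored.
#' @param seed integer seed for the perturbations and per-image noise.
#' @param perturb list of perturbation SDs: `baseline` (gray levels),
#'   `amp_frac` and `sigma_frac` (fractions of the central term's amplitude
#'   and width), and `vignette` (absolute SD of the vignette strength;
#'   healthy eyes differ in peripheral shading, which is what keeps the
#'   envelope from collapsing at high eccentricity, where a pure
#'   gray-level offset would be normalized away).
#' @return list of `n` [af_image()] objects.
#' @export
gen_control_phantoms <- function(n, base_spec = phantom_spec(), seed = 1L,
                                 perturb = list(baseline = 4, amp_frac = 0.05,
                                                sigma_frac = 0.05,
                                                vignette = 0.03)) {
  if (n < 2) stop("n must be >= 2 (control SD undefined otherwise)")
  validate_phantom_spec(base_spec)
  p <- utils::modifyList(list(baseline = 4, amp_frac = 0.05,
                              sigma_frac = 0.05, vignette = 0.03), perturb)
  degenerate <- all(unlist(p) == 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  d_base <- stats::rnorm(n, 0, p$baseline)
  d_amp <- stats::rnorm(n, 0, p$amp_frac)
  d_sig <- stats::rnorm(n, 0, p$sigma_frac)
  d_vig <- stats::rnorm(n, 0, p$vignette)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  lapply(seq_len(n), function(i) {
    s <- base_spec
    s$ring_ecc <- NULL
    s$hypo_core_ecc <- NULL
    s$baseline <- s$baseline + d_base[i]
    s$vignette_strength <- min(1, max(0, s$vignette_strength + d_vig[i]))
    if (s$modality == "SW") {
      s$fovea_dip_depth <- s$fovea_dip_depth * (1 + d_amp[i])
      s$fovea_dip_sigma <- s$fovea_dip_sigma * (1 + d_sig[i])
    } else {
      s$peak_amp <- s$peak_amp * (1 + d_amp[i])
      s$peak_sigma <- s$peak_sigma * (1 + d_sig[i])
    }
    s$seed <- if (degenerate) base_spec$seed else sub_seeds[i]
    out <- gen_af_phantom(s)$image
    out$id <- sprintf("control-%s-%02d", s$modality, i)
    out
  })
}

#' Simulate a cohort with age-dependent NIR-AF hypoautofluorescence
#'
#' Generates `n` synthetic patients with the statistical structure the
#' cohort analyses assume: the probability of a central NIR-AF
#' hypoautofluorescent core increases with age (logistic in age), the core
#' half-width grows linearly with age among affected patients
#' (`core_ecc = a + b * age + eps`), and the OCT ISe defect width tracks the
#' hypoAF diameter (`ise_width = c * hypo_diameter + delta`). Optionally
#' renders the paired SW/NIR phantom images for each patient so the full
#' image-to-statistics pipeline can be exercised.
#'
#' @param n number of patients (>= 4).
#' @param effect list of generative parameters: `age_range` (years,
#'   uniform), `hypo_age50`/`hypo_age_scale` (logistic age at 50% core
#'   probability and its scale, years), `a` (deg), `b` (deg/year,
#'   >= 0), `eps_sd` (deg), `c` (dimensionless, >= 0), `delta_sd` (deg),
#'   `ring_prob`, `ring_ecc_range` (deg).
#' @param seed integer seed.
#' @param images render the paired SW/NIR phantoms (`TRUE`) or return the
#'   truth table only (`FALSE`).
#' @param base_sw,base_nir template [phantom_spec()]s for the rendered
#'   pairs; defaults use compact 256 px images for speed.
#' @return list with `cohort` (an [as_cohort()] truth table including
#'   `hypo_diameter_deg`, `ring_diameter_deg`, `ise_width_deg`) and
#'   `patients` (when `images = TRUE`, per-patient lists with `sw`, `nir`
#'   [af_image()]s and their truths).
#' @export
gen_cohort <- function(n,
                       effect = list(),
                       seed = 1L, images = TRUE,
                       base_sw = NULL, base_nir = NULL) {
  if (n < 4) stop("n must be >= 4 (correlations degenerate below that)")
  eff <- utils::modifyList(
    list(age_range = c(8, 45), hypo_age50 = 23, hypo_age_scale = 5,
         a = 0.2, b = 0.03, eps_sd = 0.08,
         c = 1.0, delta_sd = 0.15,
         ring_prob = 0.75, ring_ecc_range = c(0.6, 2.2)),
    effect)
  if (eff$b < 0 || eff$c < 0) stop("effect slopes b and c must be >= 0")
  if (eff$eps_sd < 0 || eff$delta_sd < 0) stop("noise scales must be >= 0")
  small <- function(modality) phantom_spec(
    width = 256, height = 256, scale = 30 / 256,
    fovea = c(128, 128), disc_center = c(208, 128), disc_radius = 20,
    modality = modality, noise_sigma = 2, blur_len = 3)
  if (is.null(base_sw)) base_sw <- small("SW")
  if (is.null(base_nir)) base_nir <- small("NIR")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  age <- round(stats::runif(n, eff$age_range[1], eff$age_range[2]), 1)
  affected <- stats::rbinom(n, 1, stats::plogis(
    (age - eff$hypo_age50) / eff$hypo_age_scale)) == 1
  core_ecc <- ifelse(
    affected,
    pmax(0.15, eff$a + eff$b * age + stats::rnorm(n, 0, eff$eps_sd)),
    NA_real_)
  hypo_diam <- ifelse(affected, 2 * core_ecc, NA_real_)
  ise_width <- ifelse(
    affected,
    pmax(0.05, eff$c * hypo_diam + stats::rnorm(n, 0, eff$delta_sd)),
    0)
  ring <- stats::runif(n) < eff$ring_prob
  ring_ecc <- ifelse(ring, stats::runif(n, eff$ring_ecc_range[1],
                                        eff$ring_ecc_range[2]), NA_real_)
  stage <- ifelse(!affected, ifelse(ise_width > 0, 2L, 1L),
                  pmin(4L, 2L + findInterval(core_ecc, c(0.45, 0.8))))
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * n), ncol = 2)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  cohort <- data.frame(
    id = seq_len(n), age = age,
    sex = rep(c("F", "M"), length.out = n),
    gene = rep(c("CNGA3", "CNGB3"), length.out = n),
    mutation1 = "synthetic", mutation2 = "synthetic",
    photophobia = TRUE, nystagmus = TRUE, color_vision = "severe",
    bcva_od = "20/200", bcva_os = "20/200",
    se_od = 0.25, se_os = 0.25,
    oct_stage = stage, foveal_hypoplasia = FALSE,
    swaf_ring = ring,
    niraf_hypo = ifelse(affected, "present", "absent"),
    ise_width_deg = ise_width, study_eye = "OD",
    ring_diameter_deg = ifelse(ring, 2 * ring_ecc, NA_real_),
    hypo_diameter_deg = hypo_diam,
    stringsAsFactors = FALSE)
  cohort <- as_cohort(cohort, source = sprintf("gen_cohort(n=%d, seed=%d)", n, seed))

  patients <- NULL
  if (images) {
    patients <- lapply(seq_len(n), function(i) {
      sw <- base_sw
      sw$ring_ecc <- if (ring[i]) ring_ecc[i] else NULL
      sw$seed <- sub_seeds[i, 1]
      nir <- base_nir
      nir$hypo_core_ecc <- if (affected[i]) core_ecc[i] else NULL
      nir$seed <- sub_seeds[i, 2]
      sw_out <- gen_af_phantom(sw)
      nir_out <- gen_af_phantom(nir)
      sw_out$image$id <- sprintf("sim%03d-SW", i)
      nir_out$image$id <- sprintf("sim%03d-NIR", i)
      list(sw = sw_out$image, nir = nir_out$image,
           truth_sw = sw_out$truth, truth_nir = nir_out$truth)
    })
  }
  list(cohort = cohort, patients = patients)
}
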