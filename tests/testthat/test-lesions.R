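test_that("ring detection recovers symmetric and asymmetric analytic rings", {
  ecc <- seq(0.05, 8, by = 0.05)
  bump <- function(center, amp = 0.4, width = 0.3)
    amp * exp(-(ecc - center)^2 / (2 * width^2))
  band <- flat_band(ecc, mean = 1, sd = 0.05)

  sym <- analytic_profile(ecc, 1 + bump(1.5))
  res <- detect_ring(sym, band)
  expect_true(res$present)
  expect_equal(res$diameter_deg, 3.0, tolerance = 0.051)

  asym <- analytic_profile(ecc, nasal = 1 + bump(1.2),
                           temporal = 1 + bump(1.8))
  res2 <- detect_ring(asym, band)
  expect_equal(res2$diameter_deg, 3.0, tolerance = 0.051)

  # profile identical to the band mean: no excess anywhere
  flat <- analytic_profile(ecc, rep(1, length(ecc)))
  res3 <- detect_ring(flat, band)
  expect_false(res3$present)
  expect_true(is.na(res3$diameter_deg))

  # excess in one hemifield only is not a ring
  one_sided <- analytic_profile(ecc, nasal = 1 + bump(1.5),
                                temporal = rep(1, length(ecc)))
  expect_false(detect_ring(one_sided, band)$present)

  # a single-point spike is diluted by the smoothing window and cannot
  # sustain a supra-envelope span on its own
  spike <- rep(1, length(ecc)); spike[30] <- 1.2
  expect_false(detect_ring(analytic_profile(ecc, spike), band)$present)
})

test_that("central hypoAF status follows the envelope semantics", {
  ecc <- seq(0.05, 8, by = 0.05)
  band <- flat_band(ecc, mean = 1, sd = 0.05)
  dip <- function(depth, half_width = 0.8, edge = 0.05)
    1 - depth * plogis((half_width - ecc) / edge)

  deep <- analytic_profile(ecc, dip(0.4), modality = "NIR")
  res <- detect_central_hypoaf(deep, band)
  expect_equal(res$status, "present")
  # re-crossing of mean - sd: 0.4*logis = 0.05 at half_width + edge*log(7)
  expected <- 2 * (0.8 + 0.05 * log(0.4 / 0.05 - 1))
  expect_equal(res$diameter_deg, expected, tolerance = 0.06)

  # ill-defined central decrease, reaching past mean - 0.5 sd but not the
  # lower envelope edge: borderline, no diameter
  shallow <- analytic_profile(ecc, dip(0.035), modality = "NIR")
  res2 <- detect_central_hypoaf(shallow, band)
  expect_equal(res2$status, "borderline")
  expect_true(is.na(res2$diameter_deg))

  # profile at/above the band mean centrally: absent
  flat <- analytic_profile(ecc, rep(1, length(ecc)), modality = "NIR")
  expect_equal(detect_central_hypoaf(flat, band)$status, "absent")

  # hemifield disagreement (deep nasal, flat temporal) is not "present"
  mixed <- analytic_profile(ecc, nasal = dip(0.4),
                            temporal = rep(1, length(ecc)), modality = "NIR")
  expect_false(detect_central_hypoaf(mixed, band)$status == "present")
})

test_that("detector output is unchanged by gray-level gain and offset", {
  img <- gen_af_phantom(small_spec("NIR", hypo_core_ecc = 0.7, seed = 4))$image
  img2 <- img
  img2$pixels <- 1.7 * img$pixels + 12
  band <- cached_band("NIR")
  r1 <- detect_central_hypoaf(semiquant_profile(img), band)
  r2 <- detect_central_hypoaf(semiquant_profile(img2), band)
  expect_equal(r1$status, r2$status)
  expect_equal(r1$diameter_deg, r2$diameter_deg, tolerance = 1e-9)
})

test_that("full-pipeline measurement recovers phantom truth (single seed)", {
  band_sw <- cached_band("SW")
  band_nir <- cached_band("NIR")
  sw <- gen_af_phantom(small_spec("SW", ring_ecc = 1.5, blur_len = 3,
                                  seed = 8))
  nir <- gen_af_phantom(small_spec("NIR", hypo_core_ecc = 0.8, blur_len = 3,
                                   seed = 8))
  m <- measure_lesions(semiquant_profile(sw$image),
                       semiquant_profile(nir$image), band_sw, band_nir)
  expect_true(m$ring_present)
  expect_equal(m$ring_diameter_deg, sw$truth$ring_diameter_deg,
               tolerance = 0.2)
  expect_equal(m$hypo_status, "present")
  expect_equal(m$hypo_diameter_deg, nir$truth$hypo_diameter_deg,
               tolerance = 0.2)

  # lesion-free eye: both detectors stay silent
  sw0 <- gen_af_phantom(small_spec("SW", seed = 9))$image
  nir0 <- gen_af_phantom(small_spec("NIR", seed = 9))$image
  m0 <- measure_lesions(semiquant_profile(sw0), semiquant_profile(nir0),
                        band_sw, band_nir)
  expect_false(m0$ring_present)
  expect_equal(m0$hypo_status, "absent")
})

test_that("observer averaging preserves status and averages diameters", {
  m1 <- structure(list(ring_present = TRUE, ring_diameter_deg = 3.0,
                       hypo_status = "present", hypo_diameter_deg = 1.5,
                       observer = "A"), class = "af_lesions")
  m2 <- structure(list(ring_present = TRUE, ring_diameter_deg = 3.2,
                       hypo_status = "present", hypo_diameter_deg = 1.7,
                       observer = "B"), class = "af_lesions")
  avg <- average_observers(m1, m2)
  expect_equal(avg$ring_diameter_deg, 3.1)
  expect_equal(avg$hypo_diameter_deg, 1.6)
  expect_equal(avg$hypo_status, "present")

  # idempotence
  same <- average_observers(m1, m1)
  expect_equal(same$ring_diameter_deg, m1$ring_diameter_deg)

  m3 <- m2; m3$hypo_status <- "absent"; m3$hypo_diameter_deg <- NA_real_
  expect_error(average_observers(m1, m3), "disagreement")
})
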