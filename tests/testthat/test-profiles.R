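test_that("radius limit is the min of disc distance and fitting circle", {
  px <- matrix(100, 768, 768)
  img <- af_image(px, fovea = c(300, 250), disc_center = c(500, 250))
  expect_equal(determine_radius_limit(img), 200L)

  # fovea 150 px from the nearest border, disc 400 px away -> border wins
  img2 <- af_image(px, fovea = c(150, 384), disc_center = c(550, 384))
  expect_equal(determine_radius_limit(img2), 150L)

  img3 <- af_image(px, fovea = c(0, 384), disc_center = c(550, 384))
  expect_error(determine_radius_limit(img3), "border")
})

test_that("hemicircle means are exact on constant and split-field images", {
  px <- matrix(77, 300, 300)
  img <- af_image(px, fovea = c(150, 150), disc_center = c(230, 150),
                  disc_radius_px = 10)
  raw <- compute_raw_profile(img, R = 60)
  expect_equal(raw$mean_nasal, rep(77, 60))
  expect_equal(raw$mean_temporal, rep(77, 60))
  expect_equal(raw$af_mean, 77)
  expect_equal(raw$af_ref, 77)
  expect_error(normalize_profile(raw, scale = 30 / 768), "degenerate")

  # left half 50, right half 100, fovea on the split, disc on the right:
  # nasal samples stay on all-100 columns (exact); temporal samples touch
  # at most the two near-meridian points of the 50/100 boundary cell
  split <- cbind(matrix(50, 400, 200), matrix(100, 400, 200))
  img2 <- af_image(split, fovea = c(200, 200), disc_center = c(330, 200),
                   disc_radius_px = 10)
  raw2 <- compute_raw_profile(img2, R = 120)
  expect_equal(raw2$mean_nasal, rep(100, 120))
  expect_true(all(abs(raw2$mean_temporal[10:120] - 50) < 2.5))
})

test_that("interpolated circle sampling agrees with per-pixel radius binning", {
  # full acquisition geometry (768 px, 30-degree field): the half-gray-level
  # agreement bound presumes the gentle per-pixel slopes of that scale, and
  # circles must stay clear of the sharp disc edge (200 - 50 = 150 px)
  spec <- phantom_spec(ring_ecc = 1.5, noise_sigma = 0, blur_len = 0,
                       vignette_strength = 0)
  img <- gen_af_phantom(spec)$image
  R <- 145L
  raw <- compute_raw_profile(img, R = R)
  full_circle <- (raw$mean_nasal + raw$mean_temporal) / 2
  binned <- semiqaf:::bin_radial_means(img$pixels, img$fovea, R)
  expect_true(all(abs(full_circle[1:(R - 1)] - binned[1:(R - 1)]) < 0.5))
})

test_that("normalization fixed points, affine invariance and resampling grid", {
  raw <- structure(
    list(radii_px = 1:100, mean_nasal = rep(80, 100),
         mean_temporal = rep(20, 100), af_ref = 20, af_mean = 80, R = 100L,
         source = list(id = "synthetic", modality = "SW", laterality = "OD")),
    class = "af_raw_profile")
  prof <- normalize_profile(raw, scale = 30 / 768)
  expect_true(all(prof$af_nasal == 1))     # AF_measured = AF_mean -> 1
  expect_true(all(prof$af_temporal == 0))  # AF_measured = AF_ref  -> 0
  expect_equal(min(prof$ecc_deg), 0.05)
  expect_equal(diff(prof$ecc_deg)[1], 0.05)
  expect_lte(max(prof$ecc_deg), 100 * 30 / 768 + 1e-12)

  # gain 2, offset +10 on every pixel: identical normalized profile
  spec <- small_spec("SW", ring_ecc = 1.2, noise_sigma = 2, blur_len = 3)
  img <- gen_af_phantom(spec)$image
  img2 <- img
  img2$pixels <- 2 * img$pixels + 10
  p1 <- semiquant_profile(img)
  p2 <- semiquant_profile(img2)
  expect_equal(p1$af_nasal, p2$af_nasal, tolerance = 1e-9)
  expect_equal(p1$af_temporal, p2$af_temporal, tolerance = 1e-9)
})

test_that("mirroring an image swaps the nasal and temporal profiles exactly", {
  spec <- small_spec("NIR", hypo_core_ecc = 0.6, noise_sigma = 2)
  img <- gen_af_phantom(spec)$image
  w <- ncol(img$pixels)
  mir <- af_image(img$pixels[, w:1],
                  modality = img$modality, laterality = "OS",
                  scale = img$scale,
                  fovea = c(w - 1 - img$fovea[1], img$fovea[2]),
                  disc_center = c(w - 1 - img$disc_center[1],
                                  img$disc_center[2]),
                  disc_radius_px = img$disc_radius_px)
  p <- semiquant_profile(img)
  pm <- semiquant_profile(mir)
  expect_equal(p$af_nasal, pm$af_nasal, tolerance = 1e-9)
  expect_equal(p$af_temporal, pm$af_temporal, tolerance = 1e-9)
})

test_that("control band pools hemifield-averaged profiles with sample SD", {
  ecc <- seq(0.05, 5, by = 0.05)
  p8 <- replicate(8, analytic_profile(ecc, rep(1.1, length(ecc))),
                  simplify = FALSE)
  band <- build_control_band(p8)
  expect_true(all(band$sd == 0))
  expect_equal(band$mean, rep(1.1, length(band$ecc_deg)))
  expect_equal(band$n_controls, 8L)

  # two profiles at 0.8 and 1.2: mean 1.0, sample SD sqrt(2)*0.2
  p2 <- list(analytic_profile(ecc, rep(0.8, length(ecc))),
             analytic_profile(ecc, rep(1.2, length(ecc))))
  band2 <- build_control_band(p2)
  expect_equal(unique(band2$mean), 1.0)
  expect_equal(unique(band2$sd), 0.2 * sqrt(2), tolerance = 1e-6)

  expect_error(build_control_band(p2[1]), "at least 2")
  disjoint <- list(analytic_profile(seq(0.05, 2, 0.05), rep(1, 40)),
                   analytic_profile(seq(5, 7, 0.05), rep(1, 41)))
  expect_error(build_control_band(disjoint), "disjoint")
})

test_that("control band from simulated healthy eyes covers their noiseless profile", {
  band <- cached_band("SW")
  clean <- gen_af_phantom(small_spec("SW", noise_sigma = 0, blur_len = 0))$image
  prof <- semiquant_profile(clean)
  avg <- (prof$af_nasal + prof$af_temporal) / 2
  avg <- approx(prof$ecc_deg, avg, xout = band$ecc_deg, rule = 2)$y
  frac_in <- mean(abs(avg - band$mean) <= 3 * band$sd)
  expect_gte(frac_in, 0.99)
})

test_that("profile and band CSV exports carry the documented columns", {
  spec <- small_spec("SW")
  prof <- semiquant_profile(gen_af_phantom(spec)$image)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  tab <- utils::read.csv(f)
  expect_named(tab, c("ecc_deg", "af_nasal", "af_temporal", "modality",
                      "image_id"))
  expect_equal(tab$af_nasal, prof$af_nasal, tolerance = 1e-9)

  band <- cached_band("SW")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_band_csv(band, f2)
  tab2 <- utils::read.csv(f2)
  expect_named(tab2, c("ecc_deg", "mean", "sd", "n"))
  expect_equal(unique(tab2$n), 8L)
})
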