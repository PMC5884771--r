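#' Maximum profiling radius for an image
#'
#' The hemicircular ROIs extend from radius 1 to R pixels around the fovea.
#' R is the largest radius such that (i) no circle extends beyond the image
#' border and (ii) no circle reaches the optic-disc center:
#' `R = floor(min(distance(fovea, disc_center), distance(fovea, nearest
#' border)))`. With typical landmark geometry this falls in the 160-200 px
#' range quoted for 30-degree acquisitions.
#'
#' @param image an [af_image()].
#' @return integer radius R in pixels (>= 1).
#' @export
determine_radius_limit <- function(image) {
  stopifnot(inherits(image, "af_image"))
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  fx <- image$fovea[1]; fy <- image$fovea[2]
  d_disc <- sqrt(sum((image$fovea - image$disc_center)^2))
  d_border <- min(fx, fy, (w - 1) - fx, (h - 1) - fy)
  R <- floor(min(d_disc, d_border))
  if (R < 1)
    stop("fovea too close to the image border: no radius-1 circle fits")
  as.integer(R)
}

# Sample points on the half-circle of radius r (pixels) on one side of the
# vertical meridian through the fovea. Angular steps are chosen so the arc
# length between samples is <= 1 px; sampling at interval midpoints keeps
# every sample strictly off the vertical meridian (the tie-break excludes
# meridian points from both hemifields).
half_circle_points <- function(fovea, r, side) {
  m <- max(4L, ceiling(pi * r))
  theta <- -pi / 2 + (seq_len(m) - 0.5) * pi / m
  dx <- r * cos(theta)   # > 0 strictly
  list(x = fovea[1] + side * dx, y = fovea[2] + r * sin(theta))
}

#' Raw hemicircular mean-intensity profile
#'
#' For every integer radius r in 1..R the mean gray level is computed along
#' the nasal and the temporal semicircle centered on the fovea (bilinear
#' interpolation, arc steps <= 1 px). The vertical line through the fovea
#' splits the hemifields; the half containing the optic-disc center is
#' nasal. Alongside the per-radius means the two normalization constants are
#' extracted: `af_ref`, the mean gray level over the disc-centered circular
#' ROI (the optic nerve head carries essentially no autofluorescence), and
#' `af_mean`, the mean gray level of the full image.
#'
#' @param image an [af_image()].
#' @param R maximum radius in pixels; defaults to
#'   [determine_radius_limit()].
#' @param ref_radius_px radius of the disc reference ROI (default the
#'   image's `disc_radius_px`).
#' @return an `af_raw_profile`: list with `radii_px`, `mean_nasal`,
#'   `mean_temporal`, `af_ref`, `af_mean`, `R`, `source`.
#' @export
compute_raw_profile <- function(image, R = determine_radius_limit(image),
                                ref_radius_px = image$disc_radius_px) {
  stopifnot(inherits(image, "af_image"))
  R <- as.integer(R)
  if (R < 1) stop("R must be >= 1")
  px <- image$pixels
  w <- ncol(px); h <- nrow(px)
  dc <- image$disc_center
  if (dc[1] - ref_radius_px < 0 || dc[1] + ref_radius_px > w - 1 ||
      dc[2] - ref_radius_px < 0 || dc[2] + ref_radius_px > h - 1)
    stop("disc reference ROI clipped by the image border")
  d_border <- min(image$fovea[1], image$fovea[2],
                  (w - 1) - image$fovea[1], (h - 1) - image$fovea[2])
  if (R > d_border)
    stop("R exceeds the largest circle fitting inside the image")

  # disc reference: mean over pixels within ref_radius_px of the disc center
  xs <- seq(floor(dc[1] - ref_radius_px), ceiling(dc[1] + ref_radius_px))
  ys <- seq(floor(dc[2] - ref_radius_px), ceiling(dc[2] + ref_radius_px))
  dist2 <- outer((ys - dc[2])^2, (xs - dc[1])^2, "+")
  roi <- px[ys + 1, xs + 1, drop = FALSE][dist2 <= ref_radius_px^2]
  af_ref <- mean(roi)
  af_mean <- mean(px)

  nasal_side <- if (dc[1] >= image$fovea[1]) 1 else -1
  mean_nasal <- numeric(R); mean_temporal <- numeric(R)
  for (r in seq_len(R)) {
    pn <- half_circle_points(image$fovea, r, nasal_side)
    pt <- half_circle_points(image$fovea, r, -nasal_side)
    mean_nasal[r] <- mean(bilinear_sample(px, pn$x, pn$y))
    mean_temporal[r] <- mean(bilinear_sample(px, pt$x, pt$y))
  }
  structure(
    list(radii_px = seq_len(R), mean_nasal = mean_nasal,
         mean_temporal = mean_temporal, af_ref = af_ref, af_mean = af_mean,
         R = R,
         source = list(id = image$id, modality = image$modality,
                       laterality = image$laterality,
                       disc_dist_px = sqrt(sum((image$fovea -
                                                image$disc_center)^2)))),
    class = "af_raw_profile")
}

#' Normalize a raw profile and convert to degrees
#'
#' Applies the reference normalization
#' `AF(r) = (AF_measured(r) - AF_ref) / (AF_mean - AF_ref)` to each
#' hemifield, converts radii to eccentricity in degrees (`r * scale`) and
#' resamples both curves by linear interpolation onto a fixed eccentricity
#' grid (default step 0.05 deg) spanning `(0, R * scale]`. Grid points
#' inside the innermost sampled radius take the innermost value.
#'
#' A normalized value of 1 is the image-average autofluorescence and 0 the
#' optic-nerve-head reference; the output is invariant under any gain/offset
#' applied to all pixels.
#'
#' @param raw an `af_raw_profile` from [compute_raw_profile()].
#' @param scale degrees per pixel.
#' @param grid_step eccentricity grid step in degrees.
#' @return an `af_profile`: list with `ecc_deg`, `af_nasal`, `af_temporal`,
#'   `source`.
#' @export
normalize_profile <- function(raw, scale, grid_step = 0.05) {
  stopifnot(inherits(raw, "af_raw_profile"), scale > 0, grid_step > 0)
  denom <- raw$af_mean - raw$af_ref
  if (abs(denom) < 1e-9)
    stop("degenerate normalization: AF_mean equals AF_ref (constant image?)")
  ecc_src <- raw$radii_px * scale
  grid <- seq(grid_step, raw$R * scale, by = grid_step)
  if (!length(grid))
    stop("profile extent smaller than one grid step")
  interp <- function(v) {
    af <- (v - raw$af_ref) / denom
    stats::approx(ecc_src, af, xout = grid, rule = 2)$y
  }
  source <- raw$source
  if (!is.null(source$disc_dist_px))
    source$disc_ecc_deg <- source$disc_dist_px * scale
  structure(
    list(ecc_deg = grid, af_nasal = interp(raw$mean_nasal),
         af_temporal = interp(raw$mean_temporal), source = source),
    class = "af_profile")
}

#' One-call semiquantitative profile from an image
#'
#' Convenience wrapper: [determine_radius_limit()], [compute_raw_profile()],
#' [normalize_profile()] with the image's own scale.
#'
#' @inheritParams compute_raw_profile
#' @inheritParams normalize_profile
#' @return an `af_profile`.
#' @export
semiquant_profile <- function(image, R = determine_radius_limit(image),
                              ref_radius_px = image$disc_radius_px,
                              grid_step = 0.05) {
  raw <- compute_raw_profile(image, R = R, ref_radius_px = ref_radius_px)
  normalize_profile(raw, scale = image$scale, grid_step = grid_step)
}

#' @export
print.af_profile <- function(x, ...) {
  cat(sprintf("<af_profile '%s'> %s %s, eccentricity %.2f-%.2f deg (%d points)\n",
              x$source$id, x$source$modality, x$source$laterality,
              min(x$ecc_deg), max(x$ecc_deg), length(x$ecc_deg)))
  invisible(x)
}

#' Pointwise control envelope from healthy-eye profiles
#'
#' The two hemifields of each control profile are averaged, then the
#' pointwise mean and sample standard deviation (n-1 denominator) are taken
#' across control eyes over the common eccentricity range. The resulting
#' mean +/- SD band is the reference envelope patient profiles are plotted
#' against and compared with.
#'
#' @param profiles list of >= 2 [`af_profile`] objects on the same grid
#'   step.
#' @return an `af_band`: list with `ecc_deg`, `mean`, `sd`, `n_controls`.
#' @export
build_control_band <- function(profiles) {
  if (length(profiles) < 2L)
    stop("at least 2 control profiles are required (SD undefined otherwise)")
  stopifnot(all(vapply(profiles, inherits, TRUE, "af_profile")))
  lo <- max(vapply(profiles, function(p) min(p$ecc_deg), 1.0))
  hi <- min(vapply(profiles, function(p) max(p$ecc_deg), 1.0))
  if (lo >= hi)
    stop("control profiles have disjoint eccentricity ranges")
  grid <- profiles[[1]]$ecc_deg
  grid <- grid[grid >= lo - 1e-9 & grid <= hi + 1e-9]
  vals <- vapply(profiles, function(p) {
    avg <- (p$af_nasal + p$af_temporal) / 2
    stats::approx(p$ecc_deg, avg, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  structure(
    list(ecc_deg = grid, mean = rowMeans(vals),
         sd = apply(vals, 1, stats::sd), n_controls = length(profiles)),
    class = "af_band")
}

#' @export
print.af_band <- function(x, ...) {
  cat(sprintf("<af_band> n=%d controls, eccentricity %.2f-%.2f deg, mean AF %.2f-%.2f\n",
              x$n_controls, min(x$ecc_deg), max(x$ecc_deg),
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' Export a normalized profile to CSV
#'
#' Columns: `ecc_deg`, `af_nasal`, `af_temporal`, `modality`, `image_id`.
#'
#' @param profile an `af_profile`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "af_profile"))
  utils::write.csv(
    data.frame(ecc_deg = profile$ecc_deg, af_nasal = profile$af_nasal,
               af_temporal = profile$af_temporal,
               modality = profile$source$modality,
               image_id = profile$source$id),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a control band to CSV (columns `ecc_deg`, `mean`, `sd`, `n`)
#' @param band an `af_band`.
#' @param path output CSV path.
#' @export
write_band_csv <- function(band, path) {
  stopifnot(inherits(band, "af_band"))
  utils::write.csv(
    data.frame(ecc_deg = band$ecc_deg, mean = band$mean, sd = band$sd,
               n = band$n_controls),
    path, row.names = FALSE)
  invisible(path)
}
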