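# Centered moving average over a window in degrees; partial windows at the
# edges average over the available points.
smooth_profile_values <- function(ecc, values, window_deg = 0.25) {
  step <- stats::median(diff(ecc))
  half <- max(0L, floor((window_deg / step - 1) / 2 + 1e-9))
  if (half == 0L) return(values)
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(values[lo:hi])
  }
  out
}

# Interpolate band mean/sd onto a profile's grid; error if the band does not
# cover the requested range.
band_on_grid <- function(band, ecc) {
  if (min(ecc) < min(band$ecc_deg) - 1e-6 ||
      max(ecc) > max(band$ecc_deg) + 1e-6)
    stop("control band does not cover the profile's eccentricity range")
  list(mean = stats::approx(band$ecc_deg, band$mean, xout = ecc, rule = 2)$y,
       sd = stats::approx(band$ecc_deg, band$sd, xout = ecc, rule = 2)$y)
}

#' Detect and size the SW-AF perifoveal hyperautofluorescent ring
#'
#' The profile is smoothed by a moving average (`smooth_deg`), and each
#' hemifield is scanned in the perifoveal search range for a contiguous span
#' of at least `min_span_deg` where the smoothed profile exceeds the control
#' envelope's upper edge (`band mean + band_mult * SD`). The ring is present
#' only when both hemifields qualify; its diameter is the sum of the two
#' hemifields' maximal-excess peak eccentricities (peak-to-peak, in
#' degrees).
#'
#' @param profile an SW [`af_profile`].
#' @param band an [`af_band`] covering the search range.
#' @param search range of eccentricities (degrees) searched for the ring.
#' @param disc_clearance_deg peripapillary exclusion margin: when the
#'   profile records its fovea-to-disc distance, the search stops this many
#'   degrees before the disc center (nominal disc radius plus smoothing
#'   margin), because the hemifield-averaged control band is not a valid
#'   reference once the nasal semicircles touch the optic disc.
#' @param band_mult multiplier of the band SD defining the upper envelope.
#' @param min_span_deg minimal contiguous supra-envelope span.
#' @param smooth_deg moving-average window.
#' @return list `(present, diameter_deg)`; `diameter_deg` is `NA` when
#'   absent.
#' @export
detect_ring <- function(profile, band, search = c(0.3, 8),
                        disc_clearance_deg = 2.6, band_mult = 1,
                        min_span_deg = 0.25, smooth_deg = 0.25) {
  stopifnot(inherits(profile, "af_profile"), inherits(band, "af_band"))
  if (profile$source$modality != "SW")
    warning("ring detection is defined for SW-AF profiles")
  ecc <- profile$ecc_deg
  env <- band_on_grid(band, ecc)
  upper <- env$mean + band_mult * env$sd
  hi <- search[2]
  if (!is.null(profile$source$disc_ecc_deg))
    hi <- min(hi, profile$source$disc_ecc_deg - disc_clearance_deg)
  in_range <- ecc >= search[1] & ecc <= hi
  step <- stats::median(diff(ecc))
  min_pts <- max(1L, round(min_span_deg / step))

  peak_for <- function(values) {
    sm <- smooth_profile_values(ecc, values, smooth_deg)
    excess <- sm - upper
    qualifying <- excess > 0 & in_range
    runs <- rle(qualifying)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- runs$values & runs$lengths >= min_pts
    if (!any(ok)) return(NA_real_)
    idx <- unlist(mapply(seq, starts[ok], ends[ok], SIMPLIFY = FALSE))
    ecc[idx[which.max(excess[idx])]]
  }
  pn <- peak_for(profile$af_nasal)
  pt <- peak_for(profile$af_temporal)
  if (is.na(pn) || is.na(pt))
    list(present = FALSE, diameter_deg = NA_real_)
  else
    list(present = TRUE, diameter_deg = pn + pt)
}

#' Detect and size the NIR-AF central hypoautofluorescent area
#'
#' On the smoothed profile, the central region (eccentricity up to
#' `center_max_deg`) of each hemifield is compared with the control
#' envelope. Status is `"present"` when both hemifields dip below the lower
#' envelope edge (`band mean - band_mult * SD`); `"borderline"` when both
#' show an ill-defined central decrease, dipping below
#' `band mean - borderline_mult * SD` but not below the lower edge;
#' `"absent"` otherwise. (A borderline margin of a fraction of the SD is
#' required because any noisy profile falls marginally below the band mean
#' somewhere.) For present lesions the diameter is the sum over hemifields
#' of the eccentricity at which the smoothed profile re-crosses the lower
#' edge from below (linear interpolation between grid points).
#'
#' @param profile a NIR [`af_profile`].
#' @inheritParams detect_ring
#' @param center_max_deg outer limit of the central search region.
#' @param borderline_mult SD multiplier of the borderline threshold.
#' @return list `(status, diameter_deg)`; `diameter_deg` is `NA` unless
#'   `status == "present"`.
#' @export
detect_central_hypoaf <- function(profile, band, center_max_deg = 3,
                                  band_mult = 1, borderline_mult = 0.5,
                                  smooth_deg = 0.25) {
  stopifnot(inherits(profile, "af_profile"), inherits(band, "af_band"))
  if (profile$source$modality != "NIR")
    warning("central hypoAF detection is defined for NIR-AF profiles")
  ecc <- profile$ecc_deg
  env <- band_on_grid(band, ecc)
  lower <- env$mean - band_mult * env$sd
  central <- ecc <= center_max_deg

  hemi <- function(values) {
    sm <- smooth_profile_values(ecc, values, smooth_deg)
    d <- sm - lower
    below <- d < 0 & central
    res <- list(present = any(below),
                decrease = any((sm - (env$mean - borderline_mult * env$sd)) < 0 &
                                 central),
                radius = NA_real_)
    if (res$present) {
      i <- which(below)[1]
      j <- which(d >= 0 & seq_along(d) > i)
      if (!length(j)) {
        res$radius <- max(ecc)
      } else {
        j <- j[1]
        frac <- -d[j - 1] / (d[j] - d[j - 1])
        res$radius <- ecc[j - 1] + frac * (ecc[j] - ecc[j - 1])
      }
    }
    res
  }
  hn <- hemi(profile$af_nasal)
  ht <- hemi(profile$af_temporal)
  if (hn$present && ht$present)
    list(status = "present", diameter_deg = hn$radius + ht$radius)
  else if (hn$decrease && ht$decrease)
    list(status = "borderline", diameter_deg = NA_real_)
  else
    list(status = "absent", diameter_deg = NA_real_)
}

#' Measure both lesions of one eye
#'
#' Applies [detect_ring()] to the SW profile and [detect_central_hypoaf()]
#' to the NIR profile and bundles the result.
#'
#' @param sw_profile,nir_profile [`af_profile`]s of the same eye.
#' @param band_sw,band_nir matching control [`af_band`]s.
#' @param observer observer label stored with the measure.
#' @param ... thresholds passed to the detectors.
#' @return an `af_lesions` list: `ring_present`, `ring_diameter_deg`,
#'   `hypo_status`, `hypo_diameter_deg`, `observer`.
#' @export
measure_lesions <- function(sw_profile, nir_profile, band_sw, band_nir,
                            observer = "auto", ...) {
  ring <- detect_ring(sw_profile, band_sw, ...)
  hypo <- detect_central_hypoaf(nir_profile, band_nir, ...)
  structure(
    list(ring_present = ring$present, ring_diameter_deg = ring$diameter_deg,
         hypo_status = hypo$status, hypo_diameter_deg = hypo$diameter_deg,
         observer = observer),
    class = "af_lesions")
}

#' @export
print.af_lesions <- function(x, ...) {
  cat(sprintf("<af_lesions> [%s] SW ring: %s%s; NIR hypoAF: %s%s\n",
              x$observer,
              if (isTRUE(x$ring_present)) "present" else "absent",
              if (is.na(x$ring_diameter_deg)) ""
              else sprintf(" (%.2f deg)", x$ring_diameter_deg),
              x$hypo_status,
              if (is.na(x$hypo_diameter_deg)) ""
              else sprintf(" (%.2f deg)", x$hypo_diameter_deg)))
  invisible(x)
}

#' Average two observers' lesion measures
#'
#' Diameters are averaged arithmetically; presence/status flags must agree
#' between the observers and are preserved. Conflicting statuses raise an
#' error rather than being silently resolved.
#'
#' @param m1,m2 `af_lesions` measures of the same eye.
#' @return an `af_lesions` with averaged diameters.
#' @export
average_observers <- function(m1, m2) {
  stopifnot(inherits(m1, "af_lesions"), inherits(m2, "af_lesions"))
  if (!identical(m1$ring_present, m2$ring_present) ||
      !identical(m1$hypo_status, m2$hypo_status))
    stop("observer disagreement on lesion status; adjudicate before averaging")
  avg <- function(a, b) {
    if (is.na(a) && is.na(b)) NA_real_ else mean(c(a, b))
  }
  structure(
    list(ring_present = m1$ring_present,
         ring_diameter_deg = avg(m1$ring_diameter_deg, m2$ring_diameter_deg),
         hypo_status = m1$hypo_status,
         hypo_diameter_deg = avg(m1$hypo_diameter_deg, m2$hypo_diameter_deg),
         observer = paste(m1$observer, m2$observer, sep = "+")),
    class = "af_lesions")
}

#' Export a lesion measure as JSON
#' @param measure an `af_lesions`.
#' @param path output JSON path.
#' @export
write_lesions_json <- function(measure, path) {
  stopifnot(inherits(measure, "af_lesions"))
  jsonlite::write_json(unclass(measure), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
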