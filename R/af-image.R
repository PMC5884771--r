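#' Construct a fundus autofluorescence image object
#'
#' An `af_image` bundles one 8-bit grayscale autofluorescence acquisition
#' with the metadata the semiquantitative analysis needs: modality (SW or
#' NIR), laterality, the degrees-per-pixel scale and the two landmarks set
#' by the observer (fovea center and optic-disc center plus a disc ROI
#' radius).
#'
#' Pixel coordinates are 0-based with the origin at the center of the
#' top-left pixel, x increasing rightwards (columns) and y downwards (rows);
#' `pixels[y + 1, x + 1]` is the gray level at `(x, y)`. Gray levels are
#' nominally 0..255 but any finite numeric matrix is accepted (the
#' normalization is affine-invariant, so rescaled intensities are valid
#' input).
#'
#' @param pixels numeric matrix of gray levels, rows = y, columns = x.
#' @param modality `"SW"` (short-wavelength, 488 nm excitation) or `"NIR"`
#'   (near-infrared, 787 nm).
#' @param laterality `"OD"` (right) or `"OS"` (left eye).
#' @param scale degrees of visual angle per pixel; the default corresponds
#'   to a 30-degree field imaged at 768 x 768.
#' @param fovea,disc_center length-2 numeric `(x, y)` landmark coordinates.
#' @param disc_radius_px radius in pixels of the circular optic-disc ROI
#'   over which the reference intensity AF_ref is averaged.
#' @param id optional image identifier carried into profile provenance.
#' @return an `af_image` object.
#' @export
af_image <- function(pixels, modality = c("SW", "NIR"),
                     laterality = c("OD", "OS"),
                     scale = 30 / 768, fovea, disc_center,
                     disc_radius_px = 15, id = "image") {
  modality <- match.arg(modality)
  laterality <- match.arg(laterality)
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            length(fovea) == 2L, length(disc_center) == 2L,
            is.numeric(scale), length(scale) == 1L)
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (scale <= 0) stop("scale (degrees per pixel) must be positive")
  if (disc_radius_px <= 0) stop("disc_radius_px must be positive")
  w <- ncol(pixels); h <- nrow(pixels)
  inside <- function(p) p[1] >= 0 && p[1] <= w - 1 && p[2] >= 0 && p[2] <= h - 1
  if (!inside(fovea)) stop("fovea landmark outside the image")
  if (!inside(disc_center)) stop("disc landmark outside the image")
  if (all(fovea == disc_center)) stop("fovea and disc center must differ")
  structure(
    list(pixels = pixels, modality = modality, laterality = laterality,
         scale = scale, fovea = as.numeric(fovea),
         disc_center = as.numeric(disc_center),
         disc_radius_px = disc_radius_px, id = id),
    class = "af_image")
}

#' @export
print.af_image <- function(x, ...) {
  cat(sprintf("<af_image '%s'> %s %s, %dx%d px, %.5f deg/px\n",
              x$id, x$modality, x$laterality,
              ncol(x$pixels), nrow(x$pixels), x$scale))
  cat(sprintf("  fovea (%.1f, %.1f); disc (%.1f, %.1f) r=%g px\n",
              x$fovea[1], x$fovea[2], x$disc_center[1], x$disc_center[2],
              x$disc_radius_px))
  invisible(x)
}

#' Read a grayscale fundus image from PNG or TIFF
#'
#' Color images are converted to grayscale by the Rec. 601 luminance
#' (0.299 R + 0.587 G + 0.114 B). Intensities are returned on the 0..255
#' scale. TIFF input requires the `tiff` package.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param ... metadata passed to [af_image()] (`modality`, `laterality`,
#'   `fovea`, `disc_center`, ...).
#' @return an `af_image`.
#' @export
read_af_image <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF images")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3L)
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else arr[, , 1]
  }
  af_image(pixels = arr * 255, id = basename(path), ...)
}

#' Write an `af_image` (or plain matrix) as an 8-bit grayscale PNG
#'
#' Gray levels are clipped to 0..255 before writing.
#'
#' @param image an `af_image` or numeric matrix.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_af_png <- function(image, path) {
  px <- if (inherits(image, "af_image")) image$pixels else image
  px <- pmin(pmax(px, 0), 255) / 255
  png::writePNG(px, path)
  invisible(path)
}

# Bilinear interpolation of image intensities at continuous 0-based (x, y).
# Points must lie within [0, w-1] x [0, h-1].
bilinear_sample <- function(pixels, x, y) {
  w <- ncol(pixels); h <- nrow(pixels)
  x0 <- pmin(floor(x), w - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), h - 2); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- pixels[cbind(y0 + 1, x0 + 1)]
  i01 <- pixels[cbind(y0 + 1, x0 + 2)]
  i10 <- pixels[cbind(y0 + 2, x0 + 1)]
  i11 <- pixels[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}
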