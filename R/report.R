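#' Headline cohort statistics
#'
#' Computes the cohort-level summaries and tests for an achromatopsia
#' cohort table: demographics, per-gene refraction splits (from the
#' right-eye spherical equivalent), imaging-feature counts, OCT stage
#' distribution, the Spearman correlation between right- and left-eye
#' acuities in LogMAR, and the NIR-AF group comparison
#' ([nir_group_analysis()]).
#'
#' @param cohort an [as_cohort()] table; defaults to the packaged
#'   16-patient fixture.
#' @param fisher_alternative passed to [nir_group_analysis()].
#' @return an `af_report` list of named summaries.
#' @examples
#' rep <- cohort_report()
#' rep$mean_age             # 25.1
#' rep$spearman_bcva$estimate   # rho = 0.82
#' @export
cohort_report <- function(cohort = fixture_table2(),
                          fisher_alternative = "one.sided") {
  stopifnot(inherits(cohort, "af_cohort"))
  refr_od <- classify_refraction(cohort$se_od)
  gene_refr <- function(g) {
    r <- refr_od[cohort$gene == g]
    c(myopia = mean(r == "myopia"), hyperopia = mean(r == "hyperopia"))
  }
  lm_od <- snellen_to_logmar(cohort$bcva_od)
  lm_os <- snellen_to_logmar(cohort$bcva_os)
  structure(
    list(
      n = nrow(cohort),
      mean_age = mean(cohort$age),
      sd_age = stats::sd(cohort$age),
      gene_counts = table(cohort$gene),
      n_swaf_ring = sum(cohort$swaf_ring, na.rm = TRUE),
      n_niraf_hypo = sum(cohort$niraf_hypo == "present"),
      n_niraf_borderline = sum(cohort$niraf_hypo == "borderline"),
      n_foveal_hypoplasia = sum(cohort$foveal_hypoplasia, na.rm = TRUE),
      stage_counts = vapply(1:4, function(s) sum(cohort$oct_stage == s), 1L),
      refraction_od = table(factor(refr_od,
        levels = c("myopia", "hyperopia", "emmetropia"))),
      refraction_by_gene = sapply(intersect(c("CNGA3", "CNGB3"),
                                            unique(cohort$gene)),
                                  gene_refr, simplify = FALSE),
      spearman_bcva = spearman_cor(lm_od, lm_os),
      nir_groups = nir_group_analysis(cohort,
        fisher_alternative = fisher_alternative)
    ),
    class = "af_report")
}

#' @export
print.af_report <- function(x, ...) {
  cat(sprintf("Cohort report (n = %d)\n", x$n))
  cat(sprintf("  mean age: %.1f +/- %.1f years\n", x$mean_age, x$sd_age))
  cat(sprintf("  SW-AF perifoveal ring: %d/%d; NIR-AF central hypoAF: %d (+%d borderline)\n",
              x$n_swaf_ring, x$n, x$n_niraf_hypo, x$n_niraf_borderline))
  cat(sprintf("  foveal hypoplasia: %d; OCT stages 1-4: %s\n",
              x$n_foveal_hypoplasia, paste(x$stage_counts, collapse = "/")))
  for (g in names(x$refraction_by_gene))
    cat(sprintf("  %s refraction: %.0f%% myopia / %.0f%% hyperopia\n", g,
                100 * x$refraction_by_gene[[g]]["myopia"],
                100 * x$refraction_by_gene[[g]]["hyperopia"]))
  cat(sprintf("  Spearman BCVA OD vs OS (LogMAR): rho = %.2f, p = %.2g\n",
              x$spearman_bcva$estimate, x$spearman_bcva$p.value))
  print(x$nir_groups)
  invisible(x)
}

#' Export a cohort report as JSON
#' @param report an `af_report` from [cohort_report()].
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "af_report"))
  out <- list(
    n = report$n, mean_age = report$mean_age, sd_age = report$sd_age,
    gene_counts = as.list(report$gene_counts),
    n_swaf_ring = report$n_swaf_ring,
    n_niraf_hypo = report$n_niraf_hypo,
    n_niraf_borderline = report$n_niraf_borderline,
    n_foveal_hypoplasia = report$n_foveal_hypoplasia,
    stage_counts = report$stage_counts,
    refraction_by_gene = report$refraction_by_gene,
    spearman_bcva_rho = unname(report$spearman_bcva$estimate),
    spearman_bcva_p = report$spearman_bcva$p.value,
    mw_age_p = report$nir_groups$mann_whitney$p.value,
    fisher_stage_p = report$nir_groups$fisher$p.value)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Combined SW/NIR semiquantitative plot
#'
#' Renders the two-panel figure used to read the semiquantitative plots:
#' one panel per modality with the nasal and temporal curves mirrored about
#' 0 degrees (temporal negative, nasal positive), the control mean +/- SD
#' band shaded, and a central striped region of total width `ise_width_deg`
#' marking the ISe defect measured on OCT.
#'
#' @param sw,nir [`af_profile`]s of the same eye.
#' @param band_sw,band_nir control [`af_band`]s.
#' @param ise_width_deg ISe defect width in degrees (0 draws no stripes).
#' @param file output file; `.png` or `.svg` decides the device.
#' @return the file path, invisibly.
#' @export
render_combined_plot <- function(sw, nir, band_sw, band_nir,
                                 ise_width_deg = 0, file = "af_plot.png") {
  stopifnot(inherits(sw, "af_profile"), inherits(nir, "af_profile"),
            ise_width_deg >= 0)
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 900, height = 700),
         svg = grDevices::svg(file, width = 9, height = 7),
         stop("unsupported plot format: .", ext))
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  panel <- function(profile, band, title) {
    x <- c(-rev(profile$ecc_deg), profile$ecc_deg)
    y <- c(rev(profile$af_temporal), profile$af_nasal)
    ylim <- range(y, band$mean + band$sd, band$mean - band$sd, 0)
    graphics::plot(x, y, type = "n", xlab = "Eccentricity (deg, temporal < 0 < nasal)",
                   ylab = "Normalized AF", main = title, ylim = ylim)
    bx <- c(-rev(band$ecc_deg), band$ecc_deg)
    bm <- c(rev(band$mean), band$mean)
    bs <- c(rev(band$sd), band$sd)
    graphics::polygon(c(bx, rev(bx)), c(bm + bs, rev(bm - bs)),
                      col = "grey85", border = NA)
    if (ise_width_deg > 0)
      graphics::rect(-ise_width_deg / 2, ylim[1], ise_width_deg / 2, ylim[2],
                     density = 15, col = "grey40", border = NA)
    graphics::lines(bx, bm, col = "grey55")
    graphics::lines(x, y, lwd = 2, col = "black")
    graphics::abline(v = 0, lty = 3)
  }
  panel(sw, band_sw, sprintf("SW-AF (%s)", sw$source$id))
  panel(nir, band_nir, sprintf("NIR-AF (%s)", nir$source$id))
  invisible(file)
}

#' Plot method for normalized profiles
#' @param x an `af_profile`.
#' @param band optional [`af_band`] to shade behind the curves.
#' @param ... passed to [graphics::plot()].
#' @export
plot.af_profile <- function(x, band = NULL, ...) {
  xs <- c(-rev(x$ecc_deg), x$ecc_deg)
  ys <- c(rev(x$af_temporal), x$af_nasal)
  graphics::plot(xs, ys, type = "n",
                 xlab = "Eccentricity (deg)", ylab = "Normalized AF", ...)
  if (!is.null(band)) {
    bx <- c(-rev(band$ecc_deg), band$ecc_deg)
    bm <- c(rev(band$mean), band$mean)
    bs <- c(rev(band$sd), band$sd)
    graphics::polygon(c(bx, rev(bx)), c(bm + bs, rev(bm - bs)),
                      col = "grey85", border = NA)
    graphics::lines(bx, bm, col = "grey55")
  }
  graphics::lines(xs, ys, lwd = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Write a machine-readable provenance record
#'
#' Records the package version, seed, timestamp and any configuration
#' passed, so a run's outputs can be reproduced.
#'
#' @param path output JSON path.
#' @param seed the run's seed.
#' @param config named list of configuration values.
#' @export
write_provenance <- function(path, seed = NA_integer_, config = list()) {
  jsonlite::write_json(
    list(package = "semiqaf",
         version = as.character(utils::packageVersion("semiqaf")),
         seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
         config = config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
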