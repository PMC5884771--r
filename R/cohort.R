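# Columns every cohort table must carry, in canonical order.  Diameter
# columns (ring_diameter_deg, hypo_diameter_deg) are optional: they exist for
# measured or simulated cohorts but are absent from the published table.
.cohort_required_cols <- c(
  "id", "age", "sex", "gene", "mutation1", "mutation2",
  "photophobia", "nystagmus", "color_vision",
  "bcva_od", "bcva_os", "se_od", "se_os",
  "oct_stage", "foveal_hypoplasia", "swaf_ring", "niraf_hypo",
  "ise_width_deg", "study_eye"
)

.cohort_optional_cols <- c("ring_diameter_deg", "hypo_diameter_deg")

#' Construct and validate a cohort table
#'
#' A cohort table is a `data.frame` (class `af_cohort`) with one row per
#' patient, mirroring the clinical/imaging variables used throughout the
#' package: demographics, genotype, symptoms, Snellen acuities, spherical
#' equivalents, the 4-level foveal OCT stage, foveal hypoplasia, the SW-AF
#' perifoveal ring flag, the 3-level NIR-AF central-hypoautofluorescence
#' status and, when available, the ISe defect width and lesion diameters in
#' degrees.
#'
#' @param records data.frame with the required columns (see
#'   [read_cohort_csv()] for the schema).
#' @param source provenance label stored as an attribute.
#' @return the validated `af_cohort` data.frame.
#' @export
as_cohort <- function(records, source = "unspecified") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    stop("cohort table must be non-empty")
  missing_cols <- setdiff(.cohort_required_cols, names(records))
  if (length(missing_cols))
    stop("cohort table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$id))
    stop("cohort ids must be unique")
  if (any(!is.finite(records$age)) || any(records$age <= 0))
    stop("ages must be positive and non-missing")
  if (!all(records$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (!all(records$color_vision %in% c("partial", "severe", "unknown")))
    stop("color_vision must be partial/severe/unknown")
  if (!all(records$oct_stage %in% 1:4))
    stop("oct_stage must be an integer in 1..4")
  if (!all(records$niraf_hypo %in% c("present", "absent", "borderline")))
    stop("niraf_hypo must be present/absent/borderline")
  if (!all(records$study_eye %in% c("OD", "OS")))
    stop("study_eye must be OD or OS")
  for (col in c("bcva_od", "bcva_os")) {
    sn <- parse_snellen(records[[col]])   # errors on malformed entries
    if (any(sn$denominator <= 0 | sn$numerator <= 0))
      stop("Snellen components must be positive in column ", col)
  }
  # a width of exactly 0 means "continuous ISe, no defect" and is only
  # coherent with stage 1; stages >= 2 have a defect of positive width
  w <- records$ise_width_deg
  known <- !is.na(w)
  if (any(known & w < 0))
    stop("ise_width_deg must be >= 0")
  bad <- known & ((w == 0) != (records$oct_stage == 1L))
  if (any(bad))
    stop("ise_width_deg must be 0 exactly for stage-1 records (rows ",
         paste(which(bad), collapse = ", "), ")")
  records$oct_stage <- as.integer(records$oct_stage)
  for (col in c("age", "se_od", "se_os", "ise_width_deg"))
    records[[col]] <- as.numeric(records[[col]])
  for (col in c("photophobia", "nystagmus", "foveal_hypoplasia", "swaf_ring"))
    records[[col]] <- as.logical(records[[col]])
  class(records) <- c("af_cohort", "data.frame")
  attr(records, "source") <- source
  records
}

#' @export
print.af_cohort <- function(x, ...) {
  cat(sprintf("Achromatopsia cohort table: %d patients (source: %s)\n",
              nrow(x), attr(x, "source")))
  cat(sprintf("  genes: %s\n",
              paste(sprintf("%s=%d", names(table(x$gene)), table(x$gene)),
                    collapse = ", ")))
  cat(sprintf("  SW-AF ring present: %d; NIR-AF hypoAF present: %d (borderline: %d)\n",
              sum(x$swaf_ring, na.rm = TRUE),
              sum(x$niraf_hypo == "present"),
              sum(x$niraf_hypo == "borderline")))
  NextMethod()
  invisible(x)
}

# ---- Snellen / LogMAR -----------------------------------------------------

parse_snellen <- function(x) {
  if (is.numeric(x)) stop("Snellen acuities must be given as 'num/den' strings")
  m <- regmatches(x, regexec("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*/\\s*([0-9]+(?:\\.[0-9]+)?)\\s*$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed Snellen fraction: ", paste(x[bad], collapse = ", "))
  num <- vapply(m, function(g) as.numeric(g[2]), 1.0)
  den <- vapply(m, function(g) as.numeric(g[3]), 1.0)
  list(numerator = num, denominator = den)
}

#' Convert Snellen acuity to LogMAR
#'
#' LogMAR = log10(denominator / numerator), so 20/20 maps to 0.0 and 20/200
#' to 1.0.
#'
#' @param snellen character vector of fractions such as `"20/200"`, or the
#'   numerator if `denominator` is supplied.
#' @param denominator optional numeric denominator(s).
#' @return numeric LogMAR values.
#' @examples
#' snellen_to_logmar("20/20")   # 0
#' snellen_to_logmar(20, 100)   # log10(5)
#' @export
snellen_to_logmar <- function(snellen, denominator = NULL) {
  if (is.null(denominator)) {
    sn <- parse_snellen(snellen)
  } else {
    sn <- list(numerator = as.numeric(snellen),
               denominator = as.numeric(denominator))
  }
  if (any(!is.finite(sn$numerator)) || any(!is.finite(sn$denominator)) ||
      any(sn$numerator <= 0) || any(sn$denominator <= 0))
    stop("Snellen numerator and denominator must be positive")
  log10(sn$denominator / sn$numerator)
}

#' Classify refraction from the spherical equivalent
#'
#' Negative diopters are myopia, positive hyperopia, exactly zero emmetropia.
#'
#' @param se numeric spherical equivalent(s) in diopters.
#' @return character vector in `{"myopia","hyperopia","emmetropia"}`.
#' @export
classify_refraction <- function(se) {
  stopifnot(is.numeric(se), all(is.finite(se)))
  ifelse(se < 0, "myopia", ifelse(se > 0, "hyperopia", "emmetropia"))
}

# ---- OCT stage encoding ---------------------------------------------------

.stage_synonyms <- list(
  "1" = c("continuous ise", "continuous inner segment ellipsoid band",
          "continuous ellipsoid zone"),
  "2" = c("ise disruption", "disrupted ise", "ellipsoid zone disruption"),
  "3" = c("ise absence", "absent ise", "ellipsoid zone absence"),
  "4" = c("hrz", "hyporeflective zone")
)

#' Encode the 4-level foveal OCT grading from its descriptor
#'
#' Stage 1 = continuous inner segment ellipsoid band (ISe), stage 2 = ISe
#' disruption, stage 3 = ISe absence, stage 4 = hyporeflective zone (HRZ).
#' Matching is case-insensitive and accepts the common synonyms listed for
#' each stage.
#'
#' @param label character descriptor(s).
#' @return integer stage(s) in 1..4.
#' @export
stage_from_label <- function(label) {
  key <- tolower(trimws(label))
  out <- rep(NA_integer_, length(key))
  for (s in names(.stage_synonyms))
    out[key %in% .stage_synonyms[[s]]] <- as.integer(s)
  if (anyNA(out))
    stop("unknown OCT stage label: ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  out
}

#' Decode an OCT stage to its canonical descriptor
#' @param stage integer stage(s) in 1..4.
#' @return character descriptor(s).
#' @export
stage_to_label <- function(stage) {
  stopifnot(all(stage %in% 1:4))
  c("continuous ISe", "ISe disruption", "ISe absence", "HRZ")[stage]
}

#' Classify color vision deficiency from 15-Hue Farnsworth errors
#'
#' At most 3 errors is "partial" (incomplete achromatopsia), 4 or more is
#' "severe" (complete achromatopsia).
#'
#' @param errors_15hue non-negative integer error count(s).
#' @return character vector in `{"partial","severe"}`.
#' @export
classify_color_vision <- function(errors_15hue) {
  stopifnot(is.numeric(errors_15hue))
  if (any(!is.finite(errors_15hue)) || any(errors_15hue < 0) ||
      any(errors_15hue != round(errors_15hue)))
    stop("errors_15hue must be non-negative integers")
  ifelse(errors_15hue <= 3, "partial", "severe")
}

# ---- CSV / JSON round trip ------------------------------------------------

#' Write a cohort table to CSV
#'
#' Flags are written as 0/1, Snellen acuities as `"20/200"`-style strings and
#' missing values as empty cells. [read_cohort_csv()] restores the identical
#' cohort.
#'
#' @param cohort an `af_cohort`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "af_cohort"))
  out <- as.data.frame(cohort)
  for (col in c("photophobia", "nystagmus", "foveal_hypoplasia", "swaf_ring"))
    out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects the schema written by [write_cohort_csv()]: one column per
#' patient-record field, flags as 0/1, Snellen acuities as `"num/den"`
#' strings, `niraf_hypo` in `{present, absent, borderline}`. Parse failures
#' name the offending row and column.
#'
#' @param path CSV file path.
#' @param source provenance label for the resulting table.
#' @return an `af_cohort`.
#' @export
read_cohort_csv <- function(path, source = path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(.cohort_required_cols, names(raw))
  if (length(missing_cols))
    stop("cohort CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("bcva_od", "bcva_os")) {
    ok <- grepl("^\\s*[0-9.]+\\s*/\\s*[0-9.]+\\s*$", raw[[col]])
    if (any(!ok))
      stop(sprintf("malformed Snellen in column '%s', row(s) %s",
                   col, paste(which(!ok), collapse = ", ")))
  }
  bad_stage <- !(raw$oct_stage %in% 1:4)
  if (any(bad_stage))
    stop(sprintf("invalid oct_stage in row(s) %s",
                 paste(which(bad_stage), collapse = ", ")))
  as_cohort(raw, source = source)
}

#' Export a cohort table as JSON
#'
#' Same schema as the CSV interchange format, one JSON object per patient.
#'
#' @inheritParams write_cohort_csv
#' @export
write_cohort_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "af_cohort"))
  jsonlite::write_json(as.data.frame(cohort), path,
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' Read a cohort table from JSON
#' @param path JSON file written by [write_cohort_json()].
#' @param source provenance label.
#' @export
read_cohort_json <- function(path, source = path) {
  raw <- jsonlite::fromJSON(path)
  as_cohort(as.data.frame(raw), source = source)
}
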