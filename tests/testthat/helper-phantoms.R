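# Shared phantom geometry (compact 256 px, 30-degree field) and cached
# control bands so expensive renders happen once per test run.

small_spec <- function(modality = "SW", ...) {
  phantom_spec(width = 256, height = 256, scale = 30 / 256,
               fovea = c(128, 128), disc_center = c(208, 128),
               disc_radius = 20, modality = modality, ...)
}

.band_cache <- new.env(parent = emptyenv())

cached_band <- function(modality, seed = 3) {
  key <- paste0(modality, "_", seed)
  if (is.null(.band_cache[[key]])) {
    ctrl <- gen_control_phantoms(8, base_spec = small_spec(modality),
                                 seed = seed)
    .band_cache[[key]] <- build_control_band(lapply(ctrl, semiquant_profile))
  }
  .band_cache[[key]]
}

# Build an af_profile directly from analytic hemifield curves (bypasses the
# image pipeline; used to probe the detectors with exactly known shapes).
analytic_profile <- function(ecc, nasal, temporal = nasal,
                             modality = "SW", id = "analytic") {
  structure(list(ecc_deg = ecc, af_nasal = nasal, af_temporal = temporal,
                 source = list(id = id, modality = modality,
                               laterality = "OD")),
            class = "af_profile")
}

flat_band <- function(ecc, mean = 1, sd = 0.05, n = 8) {
  structure(list(ecc_deg = ecc, mean = rep(mean, length(ecc)),
                 sd = rep(sd, length(ecc)), n_controls = n),
            class = "af_band")
}

# Minimal clinically-shaped cohort for the group-comparison tests.
make_test_cohort <- function(ages_present, ages_absent,
                             stages_present = rep(3, length(ages_present)),
                             stages_absent = rep(1, length(ages_absent))) {
  n <- length(ages_present) + length(ages_absent)
  stages <- c(stages_present, stages_absent)
  as_cohort(data.frame(
    id = seq_len(n),
    age = c(ages_present, ages_absent),
    sex = "F", gene = "CNGA3", mutation1 = "x", mutation2 = "x",
    photophobia = TRUE, nystagmus = FALSE, color_vision = "severe",
    bcva_od = "20/200", bcva_os = "20/200", se_od = -1, se_os = -1,
    oct_stage = stages, foveal_hypoplasia = FALSE, swaf_ring = TRUE,
    niraf_hypo = rep(c("present", "absent"),
                     c(length(ages_present), length(ages_absent))),
    ise_width_deg = ifelse(stages == 1, 0, NA_real_),
    study_eye = "OD", stringsAsFactors = FALSE), source = "test")
}
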