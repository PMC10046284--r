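#' Cohort skeleton: patient and tumor characteristics
#'
#' The 17-patient myxofibrosarcoma cohort structure the synthetic presets
#' emulate: gender, age, tumor location, FNCLCC histological grade,
#' preoperative therapy (11 treated / 6 untreated) and EORTC-STBSG
#' histopathological response score. These fields are carried as metadata
#' only; the pipeline never interprets them beyond the preoperative-therapy
#' split.
#'
#' @return Tibble with one row per patient.
#' @export
mfs_cohort_table <- function() {
  tibble::tibble(
    patient = 1:17,
    gender = c("Female", "Male", "Female", "Male", "Male", "Female", "Female",
               "Male", "Male", "Female", "Male", "Male", "Female", "Male",
               "Male", "Female", "Female"),
    age = c(77, 56, 62, 68, 55, 81, 63, 47, 64, 64, 78, 49, 70, 70, 79, 67, 66),
    location = c("Upper extremity", "Upper extremity", "Lower extremity",
                 "Trunk", "Lower extremity", "Trunk", "Upper extremity",
                 "Lower extremity", "Upper extremity", "Upper extremity",
                 "Lower extremity", "Lower extremity", "Lower extremity",
                 "Trunk", "Lower extremity", "Upper extremity",
                 "Upper extremity"),
    grade = c(2, 1, 1, 1, 2, 3, 2, 1, 2, 3, 2, 2, 2, 2, 3, 2, 2),
    therapy = c("None", "None", "Radiotherapy", "None", "None", "None",
                "None", "Radiotherapy", "Radiotherapy", "Radiotherapy",
                "Radiotherapy", "Radiotherapy", "Radiotherapy",
                "Radiotherapy", "Chemotherapy", "Radiotherapy",
                "Radiotherapy"),
    response_score = c(NA, NA, "E", NA, NA, NA, NA, "E", "E", "E", "E", "E",
                       "E", "E", "E", "E", "E"),
    preop_therapy = therapy != "None"
  )
}

# Deterministic per-case target lists. Within each preoperative-therapy
# subgroup the tumor-intensity and TBR lists are fixed spreads whose exact
# arithmetic means equal the published subgroup summaries; the spread widths
# emulate the large between-case variation the assay shows while keeping the
# subgroup comparison non-significant. Cases are paired rank-with-rank (low
# expressors have low contrast). Values are inverted 8-bit intensities.
preset_targets <- function() {
  list(
    TEM1 = list(
      mean_roi_sd = 39,
      preop = list(
        tumor = c(40, 50, 60, 70, 80, 85, 90, 100, 110, 120, 130),
        tbr = c(1.1, 1.6, 2.1, 2.6, 3.1, 3.5, 3.9, 4.4, 4.9, 5.4, 5.9)
      ),
      none = list(
        tumor = c(40, 55, 70, 80, 95, 104),
        tbr = c(1.05, 1.25, 1.55, 2.15, 3.2, 4.0)
      )
    ),
    VEGFA = list(
      mean_roi_sd = 45,
      preop = list(
        tumor = c(55, 65, 75, 85, 95, 96, 100, 110, 115, 125, 135),
        tbr = c(0.8, 0.9, 1.5, 2.0, 2.5, 2.8, 3.2, 3.6, 4.0, 4.2, 4.2)
      ),
      none = list(
        tumor = c(45, 55, 65, 80, 90, 103),
        tbr = c(0.9, 1.2, 1.5, 1.9, 2.4, 2.9)
      )
    ),
    PDGFRA = list(
      mean_roi_sd = 36,
      preop = list(
        tumor = c(34, 44, 53, 61, 68, 70, 76, 83, 89, 95, 97),
        tbr = c(0.8, 0.9, 1.3, 1.6, 1.9, 2.0, 2.2, 2.4, 2.6, 2.6, 2.6)
      ),
      none = list(
        tumor = c(26, 37, 46, 56, 67, 80),
        tbr = c(0.9, 1.1, 1.4, 1.6, 1.9, 2.1)
      )
    )
  )
}

#' Available synthetic cohort presets
#' @return Character vector of preset names.
#' @export
cohort_presets <- function() names(preset_targets())

#' Per-case ground-truth targets for a synthetic cohort preset
#'
#' Each preset pins 17 cases (split 11 with / 6 without preoperative
#' therapy, following the cohort table) to deterministic target tumor
#' intensities and TBRs whose subgroup means equal the published subgroup
#' summaries exactly, and whose overall means match the published
#' per-biomarker mean intensity and mean TBR to well under the reporting
#' precision. Per-case within-ROI SD targets scale proportionally with the
#' case's intensity so their mean equals the published mean SD exactly.
#'
#' @param biomarker One of `cohort_presets()`: `"TEM1"`, `"VEGFA"`,
#'   `"PDGFRA"`.
#' @return Tibble with one row per case: `patient`, `sample_id`,
#'   `biomarker`, `preop_therapy`, `target_tumor`, `target_tbr`,
#'   `target_bg`, `target_tumor_sd`.
#' @export
cohort_preset <- function(biomarker = cohort_presets()) {
  if (length(biomarker) != 1 || !biomarker %in% cohort_presets()) {
    stop("unknown preset ", paste(sQuote(biomarker), collapse = ", "),
         "; available presets: ", paste(cohort_presets(), collapse = ", "),
         call. = FALSE)
  }
  tg <- preset_targets()[[biomarker]]
  meta <- mfs_cohort_table()
  preop_ids <- meta$patient[meta$preop_therapy]
  none_ids <- meta$patient[!meta$preop_therapy]
  df <- dplyr::bind_rows(
    tibble::tibble(patient = preop_ids, preop_therapy = TRUE,
                   target_tumor = tg$preop$tumor, target_tbr = tg$preop$tbr),
    tibble::tibble(patient = none_ids, preop_therapy = FALSE,
                   target_tumor = tg$none$tumor, target_tbr = tg$none$tbr)
  ) |>
    dplyr::arrange(patient) |>
    dplyr::mutate(
      biomarker = biomarker,
      sample_id = sprintf("%s_case%02d", biomarker, patient),
      target_bg = target_tumor / target_tbr,
      target_tumor_sd = tg$mean_roi_sd * target_tumor / mean(target_tumor)
    ) |>
    dplyr::relocate(patient, sample_id, biomarker, preop_therapy)
  df
}
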