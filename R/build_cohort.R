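derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 1e6) * 1009 + i * 9973 + 1)
}

#' Build a full synthetic cohort on disk
#'
#' For each of the 17 cases in a preset, calibrates the phantom's tumor and
#' background DAB density fields so that the *measured* noiseless pipeline
#' output (the end-to-end chain including the eps log-offset, stain
#' unmixing crosstalk, DAB re-rendering, grayscale inversion, and the
#' realized vacuole holes) hits the case's target mean and within-ROI SD,
#' then renders the slide with seeded OD noise and writes the PNG tile, its
#' GeoJSON annotation, a metadata CSV mirroring the cohort table, and a
#' ground-truth CSV.
#'
#' Calibration is a nested bracketed root-find per region: the base density
#' is solved against the target mean at each candidate texture amplitude,
#' and the amplitude against the target SD, on a quantile-compressed copy of
#' the realized texture; the base density is then refined on the full field.
#' The background target is inflated for the realized vacuole count so that
#' vacuole pixels (intensity 0 after inversion) are part of the measured
#' mean, as in the assay being emulated.
#'
#' @param preset Preset name (see [cohort_presets()]) or a preset tibble
#'   from [cohort_preset()].
#' @param out_dir Output directory (`images/`, `annotations/`,
#'   `metadata.csv`, `truth.csv` are created inside).
#' @param height,width Tile size (default 512).
#' @param noise_sd OD-space Gaussian noise SD (default 0.03).
#' @param vacuole_fraction Background fraction replaced by fat vacuoles.
#' @param hematoxylin_density Counterstain density.
#' @param seed Master seed; per-case seeds are derived from it.
#' @param cfg [scoring_config()] the calibration mirrors.
#' @param quiet Suppress the per-case progress line.
#' @return Invisibly, a manifest tibble (one row per case: paths, targets,
#'   calibrated densities and amplitudes).
#' @export
build_cohort <- function(preset, out_dir, height = 512, width = 512,
                         noise_sd = 0.03, vacuole_fraction = 0.08,
                         hematoxylin_density = 0.3, seed = 42,
                         cfg = scoring_config(), quiet = FALSE) {
  cases <- if (is.character(preset)) cohort_preset(preset) else preset
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), recursive = TRUE, showWarnings = FALSE)

  model <- stain_model(hdab_vectors())
  geometry <- default_geometry(height, width)
  roiset <- rasterize_rois(geometry, height, width)
  m_t <- roiset$masks$tumor
  m_b <- roiset$masks$background
  resp <- function(d) {
    pipeline_response(d, model, hema = hematoxylin_density,
                      eps = cfg$eps, i0 = cfg$i0,
                      weights = cfg$grayscale_weights)
  }

  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    case_seed <- derive_seed(seed, case$patient)
    spec0 <- phantom_spec(
      height, width, roiset = roiset,
      hematoxylin_density = hematoxylin_density,
      pixel_noise_sd = noise_sd, vacuole_fraction = vacuole_fraction,
      seed = case_seed
    )
    fields <- phantom_fields(spec0)
    m_bt <- m_b & !fields$vacuoles

    # tumor region
    t_vals <- standardize(fields$texture[m_t])
    cal_t <- calibrate_region(case$target_tumor, case$target_tumor_sd,
                              compress_quantiles(t_vals), resp)
    cal_t$d0 <- refine_d0(cal_t, t_vals, case$target_tumor, resp)

    # background region: vacuole pixels measure as 0, so tissue pixels must
    # carry a proportionally higher mean; SD scales with the same CV as the
    # tumor target
    infl <- sum(m_b) / sum(m_bt)
    bg_mean <- case$target_bg * infl
    bg_sd <- bg_mean * case$target_tumor_sd / case$target_tumor
    b_vals <- standardize(fields$texture[m_bt])
    cal_b <- calibrate_region(bg_mean, bg_sd, compress_quantiles(b_vals), resp)
    cal_b$d0 <- refine_d0(cal_b, b_vals, bg_mean, resp)

    spec <- phantom_spec(
      height, width, roiset = roiset,
      hematoxylin_density = hematoxylin_density,
      dab_density_tumor = cal_t$d0, dab_density_background = cal_b$d0,
      texture_amp_tumor = cal_t$a, texture_amp_background = cal_b$a,
      pixel_noise_sd = noise_sd, vacuole_fraction = vacuole_fraction,
      seed = case_seed
    )
    slide <- forward_model(spec)
    img_path <- file.path(out_dir, "images", paste0(case$sample_id, ".png"))
    ann_path <- file.path(out_dir, "annotations", paste0(case$sample_id, ".geojson"))
    png::writePNG(slide$image / 255, img_path)
    write_annotations(geometry, ann_path)
    if (!quiet) {
      message(sprintf("  %s: tumor d=%.4f (amp %.4f), background d=%.4f (amp %.4f)",
                      case$sample_id, cal_t$d0, cal_t$a, cal_b$d0, cal_b$a))
    }
    rows[[i]] <- dplyr::mutate(
      case,
      image = img_path, annotation = ann_path, seed = case_seed,
      dab_density_tumor = cal_t$d0, texture_amp_tumor = cal_t$a,
      dab_density_background = cal_b$d0, texture_amp_background = cal_b$a,
      noise_sd = noise_sd, vacuole_fraction = vacuole_fraction
    )
  }
  manifest <- dplyr::bind_rows(rows)

  meta <- dplyr::left_join(
    manifest[, c("patient", "sample_id", "biomarker")],
    mfs_cohort_table(), by = "patient"
  )
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  truth_cols <- setdiff(names(manifest), c("image", "annotation"))
  utils::write.csv(manifest[, truth_cols], file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# One-dimensional polish of the calibrated base density on the full
# (uncompressed) texture realization.
refine_d0 <- function(cal, full_vals, target_mean, resp) {
  g <- function(d0) mean(resp(pmax(d0 + cal$a * full_vals, 0))) - target_mean
  stats::uniroot(g, interval = cal$d0 + c(-0.05, 0.05), extendInt = "yes",
                 tol = 1e-8)$root
}
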