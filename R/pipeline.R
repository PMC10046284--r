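#' Read an image tile as a 0-255 RGB array
#'
#' Reads baseline PNG or TIFF tiles; grayscale images are expanded to three
#' channels, alpha channels are dropped.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @return H x W x 3 numeric array in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

sample_id_of <- function(path) tools::file_path_sans_ext(basename(path))

#' Score a set of slides against their annotations
#'
#' Pairs image tiles with annotation files by sample id (file name without
#' extension), runs the 5-step scoring protocol on each pair, and returns
#' (optionally writes) one score row per sample. Unpaired files are an
#' error listing the orphans; failures inside individual samples are
#' collected and reported together.
#'
#' @param images Character vector of image paths, or a cohort directory
#'   containing `images/` and `annotations/`.
#' @param annotations Character vector of GeoJSON paths (ignored when
#'   `images` is a directory).
#' @param metadata Optional metadata table (or CSV path) with `sample_id`
#'   and `biomarker` (plus any Table-style columns) to join in.
#' @param cfg [scoring_config()].
#' @param out_csv Optional path for the per-sample CSV; a JSON sidecar with
#'   the config fingerprint is written next to it.
#' @return Tibble with one row per sample (see [score_slide()]).
#' @export
score_samples <- function(images, annotations = NULL, metadata = NULL,
                          cfg = scoring_config(), out_csv = NULL) {
  if (length(images) == 1 && dir.exists(images)) {
    root <- images
    images <- sort(list.files(file.path(root, "images"), full.names = TRUE,
                              pattern = "\\.(png|tiff?)$"))
    annotations <- sort(list.files(file.path(root, "annotations"),
                                   full.names = TRUE, pattern = "\\.geojson$"))
    if (is.null(metadata) && file.exists(file.path(root, "metadata.csv"))) {
      metadata <- file.path(root, "metadata.csv")
    }
  }
  img_ids <- sample_id_of(images)
  ann_ids <- sample_id_of(annotations)
  orphans <- c(setdiff(img_ids, ann_ids), setdiff(ann_ids, img_ids))
  if (length(orphans) > 0) {
    stop("unpaired image/annotation files for sample(s): ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  }
  annotations <- annotations[match(img_ids, ann_ids)]

  if (!is.null(metadata) && is.character(metadata)) {
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  }
  model <- stain_model(hdab_vectors())
  failures <- character(0)
  rows <- purrr::map(seq_along(images), function(i) {
    tryCatch({
      img <- read_image(images[i])
      roiset <- read_annotations(annotations[i])
      bm <- NA_character_
      if (!is.null(metadata)) {
        hit <- match(img_ids[i], metadata$sample_id)
        if (!is.na(hit)) bm <- as.character(metadata$biomarker[hit])
      }
      score_slide(img, roiset, model, cfg, sample_id = img_ids[i],
                  biomarker = bm)
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", img_ids[i], conditionMessage(e)))
      NULL
    })
  })
  if (length(failures) > 0) {
    stop("scoring failed for ", length(failures), " sample(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  scores <- dplyr::bind_rows(rows)
  if (!is.null(metadata)) {
    extra <- setdiff(names(metadata), names(scores))
    scores <- dplyr::left_join(scores,
                               metadata[, c("sample_id", extra), drop = FALSE],
                               by = "sample_id")
  }
  if (!is.null(out_csv)) {
    utils::write.csv(scores, out_csv, row.names = FALSE)
    write_config_sidecar(cfg, paste0(tools::file_path_sans_ext(out_csv),
                                     "_config.json"))
  }
  scores
}

write_config_sidecar <- function(cfg, path, extra = list()) {
  jsonlite::write_json(c(unclass(cfg), extra), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Cohort-level report from per-sample scores
#'
#' Joins scores to cohort metadata, aggregates to one row per patient,
#' summarizes each biomarker, runs the preoperative-therapy subgroup
#' comparison, and shapes the per-case paired tumor/background intensities
#' for plotting. Samples that fail to join to the metadata are enumerated
#' in an error.
#'
#' @param scores Per-sample score tibble from [score_samples()] or a CSV
#'   path.
#' @param metadata Cohort metadata tibble or CSV path with `sample_id`,
#'   `patient`, `preop_therapy` (and optionally `biomarker`, `grade`,
#'   `location`).
#' @param cfg [scoring_config()].
#' @param out_dir Optional directory for `biomarker_summary.csv`,
#'   `subgroup_report.csv`, `paired_intensities.csv` and the config sidecar.
#' @return List of tibbles: `patients`, `summary`, `subgroup`, `paired`.
#' @export
cohort_report <- function(scores, metadata, cfg = scoring_config(),
                          out_dir = NULL) {
  if (is.character(scores)) scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) stop("empty score table: nothing to report", call. = FALSE)
  if (is.character(metadata)) metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  metadata <- tibble::as_tibble(metadata)

  unmatched <- setdiff(scores$sample_id, metadata$sample_id)
  if (length(unmatched) > 0) {
    stop("samples missing from metadata: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  keep <- setdiff(names(metadata), names(scores))
  joined <- dplyr::left_join(scores, metadata[, c("sample_id", keep)],
                             by = "sample_id")
  if (!"patient_id" %in% names(joined)) {
    if (!"patient" %in% names(joined)) {
      stop("metadata must identify patients (`patient` column)", call. = FALSE)
    }
    joined <- dplyr::rename(joined, patient_id = patient)
  }
  patients <- aggregate_patients(joined)
  summary <- summarize_biomarkers(patients, cfg$expression_threshold)
  subgroup <- preop_subgroup_report(patients, equal_var = cfg$equal_var,
                                    alpha = cfg$alpha)
  paired <- patients |>
    dplyr::select(patient_id, biomarker, preop_therapy, tumor_mean, bg_mean,
                  tbr) |>
    dplyr::arrange(biomarker, patient_id)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "biomarker_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(subgroup, file.path(out_dir, "subgroup_report.csv"),
                     row.names = FALSE)
    utils::write.csv(paired, file.path(out_dir, "paired_intensities.csv"),
                     row.names = FALSE)
    write_config_sidecar(cfg, file.path(out_dir, "report_config.json"))
  }
  list(patients = patients, summary = summary, subgroup = subgroup,
       paired = paired)
}

#' Generate a synthetic cohort (simulate entry point)
#'
#' Thin wrapper over [build_cohort()] that validates the preset name and
#' prints a ground-truth summary.
#'
#' @param preset_name One of [cohort_presets()].
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Passed to [build_cohort()] (canvas size, noise, etc.).
#' @return Invisibly, the cohort manifest tibble.
#' @export
simulate_cohort <- function(preset_name, out_dir, seed = 42, ...) {
  if (!preset_name %in% cohort_presets()) {
    stop("unknown preset ", sQuote(preset_name), "; available presets: ",
         paste(cohort_presets(), collapse = ", "), call. = FALSE)
  }
  manifest <- build_cohort(preset_name, out_dir, seed = seed, ...)
  message(sprintf(
    "%s: %d cases; ground-truth mean tumor intensity %.1f, mean TBR %.2f, %d case(s) with TBR < 1",
    preset_name, nrow(manifest), mean(manifest$target_tumor),
    mean(manifest$target_tbr), sum(manifest$target_tbr < 1)
  ))
  invisible(manifest)
}

#' End-to-end pipeline: simulate, score, report
#'
#' Runs [simulate_cohort()], [score_samples()] and [cohort_report()] in
#' sequence on one preset.
#'
#' @param preset_name One of [cohort_presets()].
#' @param dir Working directory for the cohort (created if needed).
#' @param seed Master seed.
#' @param cfg [scoring_config()].
#' @param ... Passed to [build_cohort()].
#' @return List: `manifest`, `scores`, plus the [cohort_report()] tables.
#' @export
run_cohort_pipeline <- function(preset_name, dir = tempfile("cohort_"),
                                seed = 42, cfg = scoring_config(), ...) {
  manifest <- simulate_cohort(preset_name, dir, seed = seed, ...)
  scores <- score_samples(dir, cfg = cfg,
                          out_csv = file.path(dir, "scores.csv"))
  report <- cohort_report(scores, file.path(dir, "metadata.csv"), cfg = cfg,
                          out_dir = file.path(dir, "report"))
  c(list(manifest = manifest, scores = scores), report)
}
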