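#' Aggregate slide scores to one row per patient
#'
#' Patients with several FFPE samples get the unweighted mean of their
#' per-sample tumor means and background means; the patient-level TBR is
#' recomputed from the averaged means (not averaged over per-sample TBRs),
#' so every patient carries exactly one tumor intensity, one background
#' intensity and one ratio.
#'
#' @param scores Tibble of slide scores (needs `patient_id`, `biomarker`,
#'   `tumor_mean`, `tumor_sd`, `bg_mean`, `tbr`); typically the output of
#'   [score_samples()] joined to cohort metadata.
#' @return Tibble with one row per patient x biomarker: `patient_id`,
#'   `biomarker`, `n_samples`, `tumor_mean`, `tumor_sd_mean`, `bg_mean`,
#'   `tbr`, plus any metadata columns (`preop_therapy`, `grade`, `location`)
#'   present in the input (first value per patient).
#' @export
aggregate_patients <- function(scores) {
  req <- c("patient_id", "biomarker", "tumor_mean", "tumor_sd", "bg_mean")
  missing_cols <- setdiff(req, names(scores))
  if (length(missing_cols) > 0) {
    stop("scores are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(scores) == 0) stop("no scores to aggregate", call. = FALSE)
  meta_cols <- intersect(c("preop_therapy", "grade", "location"), names(scores))
  out <- scores |>
    dplyr::group_by(patient_id, biomarker) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      tumor_sd_mean = mean(tumor_sd),
      dplyr::across(dplyr::all_of(meta_cols), dplyr::first),
      tumor_mean = mean(tumor_mean),
      bg_mean = mean(bg_mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(tbr = tumor_mean / bg_mean) |>
    dplyr::relocate(patient_id, biomarker, n_samples, tumor_mean,
                    tumor_sd_mean, bg_mean, tbr)
  out
}

#' Aggregate scores for a single patient and biomarker
#'
#' Strict single-group version of [aggregate_patients()]: all rows must share
#' one patient and one biomarker, otherwise a grouping error is raised.
#'
#' @param scores Slide-score rows for one patient x biomarker.
#' @return One-row tibble (see [aggregate_patients()]).
#' @export
aggregate_patient <- function(scores) {
  if (nrow(scores) == 0) stop("no scores to aggregate", call. = FALSE)
  if (length(unique(scores$biomarker)) > 1) {
    stop("cannot aggregate across biomarkers: found ",
         paste(unique(scores$biomarker), collapse = ", "), call. = FALSE)
  }
  if (!"patient_id" %in% names(scores)) scores$patient_id <- scores$sample_id[1]
  if (length(unique(scores$patient_id)) > 1) {
    stop("cannot aggregate across patients: found ",
         paste(unique(scores$patient_id), collapse = ", "), call. = FALSE)
  }
  aggregate_patients(scores)
}

#' Per-biomarker cohort summary
#'
#' @param patients Patient-level tibble from [aggregate_patients()].
#' @param expression_threshold Tumor mean intensity (inverted 0-255 scale) at
#'   or above which a biomarker counts as expressed in a patient. The cutoff
#'   is deliberately explicit configuration, not a hidden constant.
#' @return Tibble with one row per biomarker: `n_patients`,
#'   `mean_tumor_intensity`, `mean_within_roi_sd`, `mean_tbr`,
#'   `n_tbr_below_1`, `fraction_expressed`.
#' @export
summarize_biomarkers <- function(patients, expression_threshold = 10) {
  if (nrow(patients) == 0) stop("no patients to summarize", call. = FALSE)
  patients |>
    dplyr::group_by(biomarker) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      mean_tumor_intensity = mean(tumor_mean),
      mean_within_roi_sd = mean(tumor_sd_mean),
      mean_tbr = mean(tbr),
      n_tbr_below_1 = sum(tbr < 1),
      fraction_expressed = mean(tumor_mean >= expression_threshold),
      .groups = "drop"
    )
}

new_ihc_ttest <- function(ht, n, alpha, type) {
  structure(
    list(
      statistic = unname(ht$statistic), p = unname(ht$p.value),
      df = unname(ht$parameter), estimate = unname(sum(ht$estimate * c(1, -1)[seq_along(ht$estimate)])),
      conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
      n = n, alpha = alpha, significant = ht$p.value <= alpha,
      type = type, method = ht$method
    ),
    class = "ihc_ttest"
  )
}

#' Paired t-test on matched tumor and background intensities
#'
#' Two-sided paired t-test on per-patient differences (tumor minus
#' background), `t = mean(d) / (sd(d) / sqrt(n))` with n - 1 degrees of
#' freedom. Significance is called at `p <= alpha`.
#'
#' @param tumor_means,background_means Matched per-patient values.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `ihc_ttest`; see [tidy.ihc_ttest()].
#' @export
paired_t <- function(tumor_means, background_means, alpha = 0.05) {
  if (length(tumor_means) != length(background_means)) {
    stop("paired test needs equal-length vectors", call. = FALSE)
  }
  n <- length(tumor_means)
  if (n < 2) stop("paired test needs at least 2 pairs", call. = FALSE)
  d <- tumor_means - background_means
  if (stats::sd(d) == 0) {
    stop("degenerate paired test: all differences identical (zero variance)",
         call. = FALSE)
  }
  ht <- stats::t.test(tumor_means, background_means, paired = TRUE)
  new_ihc_ttest(ht, n = n, alpha = alpha, type = "paired")
}

#' Unpaired two-sample t-test
#'
#' Two-sided two-sample t-test, pooled variance by default (`equal_var =
#' FALSE` gives Welch's test).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param equal_var Pooled-variance test (default TRUE).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `ihc_ttest`.
#' @export
unpaired_t <- function(group_a, group_b, equal_var = TRUE, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = equal_var)
  res <- new_ihc_ttest(ht, n = c(n1 = length(group_a), n2 = length(group_b)),
                       alpha = alpha, type = "unpaired")
  res
}

#' @export
print.ihc_ttest <- function(x, ...) {
  cat(sprintf("<ihc_ttest> %s: t = %.4f, df = %.4g, p = %.4g (%ssignificant at alpha = %.2f)\n",
              x$type, x$statistic, x$df, x$p,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Tidy a t-test result
#'
#' @param x An `ihc_ttest` object.
#' @param ... Unused.
#' @return One-row tibble: `type`, `estimate`, `statistic`, `df`, `p_value`,
#'   `conf_low`, `conf_high`, `significant`.
#' @export
tidy.ihc_ttest <- function(x, ...) {
  tibble::tibble(
    type = x$type, estimate = x$estimate, statistic = x$statistic,
    df = x$df, p_value = x$p, conf_low = x$conf_low, conf_high = x$conf_high,
    significant = x$significant
  )
}

#' One-row model summary of a t-test result
#'
#' @param x An `ihc_ttest` object.
#' @param ... Unused.
#' @export
glance.ihc_ttest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p, df = x$df,
    n = sum(x$n), alpha = x$alpha, significant = x$significant
  )
}

#' Generic for broom-style tidying
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for broom-style one-row summaries
#' @param x Object to summarize.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Subgroup comparison by preoperative therapy
#'
#' For each biomarker, compares mean tumor intensity and mean TBR between
#' patients with and without preoperative therapy using the unpaired t-test.
#' If one subgroup is empty the report is still emitted with the p-values
#' marked not computable (NA).
#'
#' @param patients Patient-level tibble from [aggregate_patients()] with a
#'   logical `preop_therapy` column.
#' @param equal_var Pooled-variance t-test (default TRUE).
#' @param alpha Significance level.
#' @return Tibble with one row per biomarker x metric
#'   (`tumor_intensity`, `tbr`): `mean_preop`, `mean_none`, `n_preop`,
#'   `n_none`, `statistic`, `p_value`, `significant`.
#' @export
preop_subgroup_report <- function(patients, equal_var = TRUE, alpha = 0.05) {
  if (!"preop_therapy" %in% names(patients)) {
    stop("patients table needs a logical `preop_therapy` column", call. = FALSE)
  }
  metrics <- c(tumor_intensity = "tumor_mean", tbr = "tbr")
  patients |>
    dplyr::group_by(biomarker) |>
    dplyr::group_modify(function(df, key) {
      purrr::imap_dfr(metrics, function(col, metric) {
        a <- df[[col]][df$preop_therapy]
        b <- df[[col]][!df$preop_therapy]
        row <- tibble::tibble(
          metric = metric,
          mean_preop = if (length(a)) mean(a) else NA_real_,
          mean_none = if (length(b)) mean(b) else NA_real_,
          n_preop = length(a), n_none = length(b),
          statistic = NA_real_, p_value = NA_real_, significant = NA
        )
        if (length(a) >= 2 && length(b) >= 2) {
          tt <- unpaired_t(a, b, equal_var = equal_var, alpha = alpha)
          row$statistic <- tt$statistic
          row$p_value <- tt$p
          row$significant <- tt$significant
        }
        row
      })
    }) |>
    dplyr::ungroup()
}
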