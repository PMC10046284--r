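#' Paired tumor / adjacent-healthy intensity plot
#'
#' One line per patient connecting the background and tumor mean staining
#' intensities, faceted by biomarker; pairs where background exceeds tumor
#' (TBR < 1) are drawn in red.
#'
#' @param patients Patient-level tibble (from [aggregate_patients()] or the
#'   `patients` element of [cohort_report()]).
#' @return A ggplot object.
#' @export
plot_paired_intensities <- function(patients) {
  long <- patients |>
    dplyr::mutate(below_1 = tbr < 1) |>
    tidyr::pivot_longer(c(bg_mean, tumor_mean), names_to = "tissue",
                        values_to = "intensity") |>
    dplyr::mutate(tissue = factor(tissue, c("bg_mean", "tumor_mean"),
                                  c("Adjacent healthy", "Tumor")))
  ggplot2::ggplot(long, ggplot2::aes(tissue, intensity,
                                     group = patient_id, colour = below_1)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::facet_wrap(~biomarker) +
    ggplot2::labs(x = NULL, y = "Mean staining intensity (inverted, 0-255)") +
    ggplot2::theme_minimal()
}

#' Per-biomarker summary plot
#'
#' Mean TBR per biomarker with the 1.5x overexpression rule of thumb for
#' fluorescence-guided surgery marked.
#'
#' @param summary Tibble from [summarize_biomarkers()].
#' @return A ggplot object.
#' @export
plot_biomarker_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(biomarker, mean_tbr)) +
    ggplot2::geom_col(fill = "peru") +
    ggplot2::geom_hline(yintercept = 1.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Mean tumor-to-background ratio") +
    ggplot2::theme_minimal()
}

#' Display a gradient map (or any RGB array) with ggplot2
#'
#' @param img H x W x 3 array in \[0, 255\], e.g. from [gradient_map()].
#' @return A ggplot object.
#' @export
plot_rgb <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  df <- expand.grid(y = seq_len(h), x = seq_len(w))
  df$fill <- grDevices::rgb(img[, , 1] / 255, img[, , 2] / 255, img[, , 3] / 255)
  ggplot2::ggplot(df, ggplot2::aes(x, y, fill = fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
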