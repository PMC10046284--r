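#' Collapse an RGB image to grayscale
#'
#' Weighted channel average; the default equal weighting (1/3, 1/3, 1/3)
#' matches the plain RGB-to-gray conversion used by common desktop image
#' analysis tools, and luminance weights (0.299, 0.587, 0.114) are available
#' through `weights`.
#'
#' @param image H x W x 3 RGB array.
#' @param weights Three non-negative reals summing to 1.
#' @return H x W matrix with attribute `inverted = FALSE`.
#' @export
to_grayscale <- function(image, weights = c(1, 1, 1) / 3) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be three non-negative values summing to 1",
         call. = FALSE)
  }
  g <- image[, , 1] * weights[1] + image[, , 2] * weights[2] +
    image[, , 3] * weights[3]
  attr(g, "inverted") <- FALSE
  g
}

#' Invert a grayscale raster
#'
#' After inversion high pixel values correspond to high DAB density, which is
#' the scale the staining intensities and TBR are reported on.
#'
#' @param g Grayscale matrix from [to_grayscale()] (not yet inverted).
#' @return 255 - g, with attribute `inverted = TRUE`.
#' @export
invert_gray <- function(g) {
  if (isTRUE(attr(g, "inverted"))) {
    stop("raster is already inverted", call. = FALSE)
  }
  out <- 255 - g
  attr(out, "inverted") <- TRUE
  out
}

#' Mean and standard deviation of staining intensity within an ROI
#'
#' @param g Inverted grayscale raster.
#' @param mask Logical matrix of the same dimensions.
#' @return One-row tibble: `mean`, `sd` (sample SD, n - 1 denominator),
#'   `n_pixels`.
#' @export
measure_roi <- function(g, mask) {
  if (!isTRUE(attr(g, "inverted"))) {
    stop("intensity is measured on the inverted raster; call invert_gray() first",
         call. = FALSE)
  }
  if (!identical(dim(g), dim(mask))) {
    stop("raster and mask dimensions differ", call. = FALSE)
  }
  vals <- g[mask]
  n <- length(vals)
  if (n == 0) stop("ROI mask is empty", call. = FALSE)
  if (n == 1) {
    warning("single-pixel ROI: standard deviation reported as 0")
    return(tibble::tibble(mean = vals, sd = 0, n_pixels = 1L))
  }
  tibble::tibble(mean = mean(vals), sd = stats::sd(vals), n_pixels = n)
}

#' Tumor-to-background ratio
#'
#' Mean tumor-ROI staining intensity divided by mean adjacent-healthy-ROI
#' staining intensity. A ratio below 1 (background stains stronger than
#' tumor) is legal and is reported with a message; a zero background mean is
#' an error, not an infinite ratio.
#'
#' @param tumor,background One-row ROI statistics from [measure_roi()] (or
#'   anything with a `mean` element).
#' @return The ratio (single numeric).
#' @export
compute_tbr <- function(tumor, background) {
  bm <- background$mean
  if (!is.finite(bm) || bm <= 0) {
    stop("TBR undefined: background mean staining intensity is zero",
         call. = FALSE)
  }
  tbr <- tumor$mean / bm
  if (tbr < 1) {
    message(sprintf(
      "TBR %.3f < 1: staining intensity is higher in adjacent healthy tissue",
      tbr
    ))
  }
  tbr
}

#' Default scoring configuration
#'
#' @param grayscale_weights RGB-to-gray weights (default equal thirds).
#' @param eps Log-offset for optical density (intensity units).
#' @param i0 Blank-glass intensity.
#' @param clip_negative Clip negative unmixed densities.
#' @param expression_threshold Tumor mean (inverted 0-255 scale) at or above
#'   which a biomarker is called expressed in a patient.
#' @param alpha Significance level for the cohort t-tests.
#' @param equal_var Pooled-variance unpaired t-test (FALSE for Welch).
#' @return List of class `scoring_config`.
#' @export
scoring_config <- function(grayscale_weights = c(1, 1, 1) / 3,
                           eps = 1, i0 = 255, clip_negative = TRUE,
                           expression_threshold = 10,
                           alpha = 0.05, equal_var = TRUE) {
  structure(
    list(
      grayscale_weights = grayscale_weights, eps = eps, i0 = i0,
      clip_negative = clip_negative,
      expression_threshold = expression_threshold,
      alpha = alpha, equal_var = equal_var
    ),
    class = "scoring_config"
  )
}

with_step <- function(step, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("step %d: %s", step, conditionMessage(e)), call. = FALSE)
  })
}

#' Score one slide: the 5-step objective IHC protocol
#'
#' Runs the full per-sample measurement chain: (1) rasterize the annotated
#' tumor and adjacent-healthy ROIs, (2) convert to optical density and unmix
#' with the stain model, keeping the DAB channel, then re-render it as an
#' RGB image, (3) collapse to grayscale, (4) invert so high values mean high
#' DAB density, (5) measure mean/SD inside each ROI and form the
#' tumor-to-background ratio.
#'
#' @param image H x W x 3 RGB array in \[0, 255\].
#' @param roiset [roi_set()], rasterized or not.
#' @param model [stain_model()]; defaults to the H-DAB preset.
#' @param cfg [scoring_config()].
#' @param sample_id,biomarker Identifiers copied into the output row.
#' @param keep_intermediates Attach the intermediate rasters (OD, densities,
#'   rendered DAB, inverted gray) as an attribute for audit.
#' @return One-row tibble of class `slide_score`: `sample_id`, `biomarker`,
#'   `tumor_mean`, `tumor_sd`, `tumor_n`, `bg_mean`, `bg_sd`, `bg_n`, `tbr`,
#'   `tbr_below_1`, `grayscale` (weight provenance).
#' @export
score_slide <- function(image, roiset, model = stain_model(hdab_vectors()),
                        cfg = scoring_config(), sample_id = NA_character_,
                        biomarker = NA_character_, keep_intermediates = FALSE) {
  if (!"dab" %in% model$names) {
    stop("stain model has no 'dab' stain to score", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  roiset <- with_step(1, {
    if (is.null(roiset$masks)) rasterize_rois(roiset, h, w) else roiset
  })
  dab <- with_step(2, {
    od <- rgb_to_od(image, i0 = cfg$i0, eps = cfg$eps)
    dens <- deconvolve(od, model, clip_negative = cfg$clip_negative)
    dens[, , "dab"]
  })
  rendered <- with_step(2, render_stain(dab, model$matrix["dab", ],
                                        i0 = cfg$i0, bit_depth = "8bit"))
  gray <- with_step(3, to_grayscale(rendered, cfg$grayscale_weights))
  inv <- with_step(4, invert_gray(gray))
  tumor <- with_step(5, measure_roi(inv, roiset$masks$tumor))
  bg <- with_step(5, measure_roi(inv, roiset$masks$background))
  tbr <- with_step(5, suppressMessages(compute_tbr(tumor, bg)))
  out <- tibble::tibble(
    sample_id = sample_id, biomarker = biomarker,
    tumor_mean = tumor$mean, tumor_sd = tumor$sd, tumor_n = tumor$n_pixels,
    bg_mean = bg$mean, bg_sd = bg$sd, bg_n = bg$n_pixels,
    tbr = tbr, tbr_below_1 = tbr < 1,
    grayscale = paste(signif(cfg$grayscale_weights, 6), collapse = "/")
  )
  class(out) <- c("slide_score", class(out))
  if (keep_intermediates) {
    attr(out, "intermediates") <- list(dab_density = dab, rendered = rendered,
                                       inverted = inv, roiset = roiset)
  }
  out
}

#' Render a DAB intensity raster as a gradient map
#'
#' Min-max scales the raster and maps it through a perceptually monotone
#' colormap, the rendering used to delineate tumor from adjacent healthy
#' tissue at a glance. The scaling bounds are recorded in the output's
#' attributes. A constant raster is rendered at the colormap midpoint with a
#' degenerate-range warning.
#'
#' @param g Numeric matrix (inverted grayscale or DAB density).
#' @param colormap Name of a monotone `grDevices::hcl.colors` palette
#'   (default `"viridis"`).
#' @param file Optional PNG path to write the map to.
#' @return H x W x 3 RGB array (0-255) with attributes `scale_min`,
#'   `scale_max`, `colormap`.
#' @export
gradient_map <- function(g, colormap = "viridis", file = NULL) {
  if (any(!is.finite(g))) stop("raster must be finite", call. = FALSE)
  lo <- min(g); hi <- max(g)
  if (hi == lo) {
    warning("constant raster: degenerate intensity range, rendered at colormap midpoint")
    t <- matrix(0.5, nrow(g), ncol(g))
  } else {
    t <- (g - lo) / (hi - lo)
  }
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, colormap))
  rgbvals <- ramp(as.vector(t))
  out <- array(rgbvals, dim = c(nrow(g), ncol(g), 3))
  attr(out, "scale_min") <- lo
  attr(out, "scale_max") <- hi
  attr(out, "colormap") <- colormap
  if (!is.null(file)) png::writePNG(out / 255, file)
  out
}
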