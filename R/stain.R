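#' H-DAB stain absorbance preset
#'
#' Raw RGB absorbance triples for the standard hematoxylin / eosin / DAB
#' color-deconvolution preset. Rows are stains, columns are R, G, B
#' optical-density contributions. These are the canonical published
#' constants for brightfield H-DAB unmixing; alternative presets can be
#' supplied through [stain_presets()] or directly to [stain_model()].
#'
#' @return A 3x3 numeric matrix with rownames `hematoxylin`, `eosin`, `dab`.
#' @export
#' @examples
#' hdab_vectors()
hdab_vectors <- function() {
  matrix(
    c(
      0.650, 0.704, 0.286,
      0.072, 0.990, 0.105,
      0.268, 0.570, 0.776
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("hematoxylin", "eosin", "dab"), c("r", "g", "b"))
  )
}

#' Load named stain-vector presets from a YAML config
#'
#' Presets are stored as a named list of 3-element RGB absorbance triples so
#' that alternative deconvolution matrices are drop-in. The file shipped with
#' the package (`inst/extdata/stain_presets.yaml`) carries the H-DAB preset.
#'
#' @param file Path to a YAML file. Defaults to the packaged preset file.
#' @return Named list of stain matrices (rows = stains).
#' @export
stain_presets <- function(file = system.file("extdata", "stain_presets.yaml",
                                             package = "dabquant")) {
  cfg <- yaml::read_yaml(file)
  lapply(cfg, function(preset) {
    m <- do.call(rbind, lapply(preset, unlist))
    colnames(m) <- c("r", "g", "b")
    m
  })
}

#' Build a stain unmixing model
#'
#' Normalizes each stain absorbance vector to unit Euclidean norm and inverts
#' the stain matrix to obtain the per-pixel unmixing matrix. When only two
#' stains are supplied the third row is completed as the unit-norm orthogonal
#' complement (cross product) of the first two, with negative components
#' zeroed and the row re-normalized, so residual absorbance has somewhere to
#' go without contaminating the named channels.
#'
#' @param raw_vectors 2x3 or 3x3 numeric matrix of non-negative absorbance
#'   triples (rows = stains, columns = R, G, B).
#' @param names Character vector of stain labels, one per supplied row
#'   (plus `"residual"` appended when the third row is completed).
#' @return An object of class `stain_model`: list with `names`, `raw`,
#'   `matrix` (row-normalized stain matrix) and `unmix` (its inverse).
#' @export
#' @examples
#' m <- stain_model(hdab_vectors())
#' round(m$matrix %*% m$unmix, 10)
stain_model <- function(raw_vectors, names = rownames(raw_vectors)) {
  raw_vectors <- as.matrix(raw_vectors)
  if (!is.numeric(raw_vectors) || ncol(raw_vectors) != 3 ||
      !nrow(raw_vectors) %in% c(2L, 3L)) {
    stop("`raw_vectors` must be a numeric 2x3 or 3x3 matrix", call. = FALSE)
  }
  if (any(!is.finite(raw_vectors)) || any(raw_vectors < 0)) {
    stop("stain absorbance vectors must be finite and non-negative",
         call. = FALSE)
  }
  norms <- sqrt(rowSums(raw_vectors^2))
  if (any(norms <= 0)) {
    stop("each stain vector must have positive norm", call. = FALSE)
  }
  if (is.null(names)) {
    names <- paste0("stain", seq_len(nrow(raw_vectors)))
  }
  m <- raw_vectors / norms

  # pairwise collinearity check before inverting, to name the offending pair
  pairs <- utils::combn(nrow(m), 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (abs(abs(sum(m[i, ] * m[j, ])) - 1) < 1e-10) {
      stop(sprintf("stain vectors '%s' and '%s' are collinear; matrix is singular",
                   names[i], names[j]), call. = FALSE)
    }
  }

  if (nrow(m) == 2L) {
    third <- c(
      m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
      m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
      m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
    )
    third <- third / sqrt(sum(third^2))
    third <- pmax(third, 0)
    if (sum(third^2) == 0) {
      stop("orthogonal complement of the two stain vectors is non-physical",
           call. = FALSE)
    }
    third <- third / sqrt(sum(third^2))
    m <- rbind(m, third)
    names <- c(names, "residual")
  }
  rownames(m) <- names

  unmix <- tryCatch(solve(m), error = function(e) {
    stop("normalized stain matrix is singular and cannot be inverted",
         call. = FALSE)
  })
  structure(
    list(names = names, raw = raw_vectors, matrix = m, unmix = unmix),
    class = "stain_model"
  )
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model> stains:", paste(x$names, collapse = ", "), "\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert relation per channel:
#' `od = -log10((pixel + eps) / (i0 + eps))`, clipped below at zero. Blank
#' glass (pixel equal to the background intensity `i0`) maps to exactly zero
#' absorbance; darker pixels map to larger OD.
#'
#' @param image H x W x 3 numeric array of channel intensities in \[0, 255\].
#' @param i0 Background (blank-glass) intensity, scalar or per-channel,
#'   strictly positive. Default 255.
#' @param eps Small positive offset guarding against log of zero. Default 1
#'   intensity unit.
#' @return H x W x 3 array of optical densities (>= 0) with attribute `i0`.
#' @export
rgb_to_od <- function(image, i0 = 255, eps = 1) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (any(i0 <= 0)) stop("`i0` must be strictly positive", call. = FALSE)
  if (length(eps) != 1 || eps <= 0) {
    stop("`eps` must be a single positive value", call. = FALSE)
  }
  i0 <- rep_len(i0, 3)
  od <- image
  for (c in 1:3) {
    od[, , c] <- -log10((image[, , c] + eps) / (i0[c] + eps))
  }
  od[od < 0] <- 0
  attr(od, "i0") <- i0
  od
}

#' Unmix optical densities into per-stain density channels
#'
#' Per pixel, the OD triple is a non-negative combination of the stain
#' absorbance vectors; applying the model's unmixing matrix recovers the
#' per-stain densities. Small negative densities (noise leaking past the
#' stain simplex) are clipped to zero by default because densities are
#' physical concentrations.
#'
#' @param od H x W x 3 optical-density array from [rgb_to_od()].
#' @param model A [stain_model()].
#' @param clip_negative Clip negative unmixed densities to zero (default TRUE).
#' @return H x W x n_stain array of stain densities; the third dimension is
#'   named by `model$names`.
#' @export
deconvolve <- function(od, model, clip_negative = TRUE) {
  stopifnot(inherits(model, "stain_model"))
  d <- dim(od)
  if (length(d) != 3 || d[3] != 3) {
    stop("`od` must be an H x W x 3 array", call. = FALSE)
  }
  flat <- matrix(od, ncol = 3)          # pixels x channels
  dens <- flat %*% model$unmix          # pixels x stains
  if (clip_negative) dens[dens < 0] <- 0
  out <- array(dens, dim = c(d[1], d[2], nrow(model$matrix)))
  dimnames(out) <- list(NULL, NULL, model$names)
  out
}

#' Re-render a single stain density field as an RGB image
#'
#' Inverse Beer-Lambert rendering of one stain on blank glass:
#' `channel_c = i0_c * 10^(-v_c * density)`.
#'
#' @param density H x W matrix of non-negative stain densities.
#' @param stain_vector Unit absorbance triple of the stain.
#' @param i0 Background intensity (scalar or per channel), default 255.
#' @param bit_depth `"8bit"` (round and clamp to integers in \[0, 255\]) or
#'   `"continuous"` (real-valued, used by quantization-free tests).
#' @return H x W x 3 RGB array.
#' @export
render_stain <- function(density, stain_vector, i0 = 255,
                         bit_depth = c("8bit", "continuous")) {
  bit_depth <- match.arg(bit_depth)
  density <- as.matrix(density)
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("`density` must be finite and non-negative", call. = FALSE)
  }
  i0 <- rep_len(i0, 3)
  out <- array(0, dim = c(nrow(density), ncol(density), 3))
  for (c in 1:3) {
    out[, , c] <- i0[c] * 10^(-stain_vector[c] * density)
  }
  if (bit_depth == "8bit") {
    out <- pmin(pmax(round(out), 0), 255)
  }
  attr(out, "bit_depth") <- bit_depth
  out
}
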