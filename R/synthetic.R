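#' Noiseless closed-form pipeline response to DAB density
#'
#' The scoring chain maps a pure DAB absorbance `d` to an inverted-grayscale
#' intensity `f(d) = 255 * (1 - mean_c 10^(-v_c * d))` where `v` is the unit
#' DAB absorbance vector. `f` is strictly increasing, 0 at `d = 0`, and
#' saturates towards 255; it is the oracle the phantom calibration inverts.
#'
#' @param d Vector of DAB densities (>= 0).
#' @param model [stain_model()] with a `dab` stain.
#' @return Inverted-grayscale intensities, same length as `d`.
#' @export
dab_response <- function(d, model = stain_model(hdab_vectors())) {
  v <- model$matrix["dab", ]
  vapply(d, function(di) 255 * (1 - mean(10^(-v * di))), numeric(1))
}

#' Invert the noiseless pipeline response
#'
#' Bracketed root-finding on [dab_response()]: returns the DAB density whose
#' noiseless pipeline output equals `target` to within 1e-6 intensity units.
#' Targets at or beyond the attainable maximum (the response saturates below
#' 255) raise a calibration error stating that maximum.
#'
#' @param target Inverted-grayscale mean on the 0-255 scale.
#' @param model [stain_model()].
#' @param d_max Upper bracket for the density search (default 10).
#' @return DAB density `d` with `|f(d) - target| <= 1e-6`.
#' @export
calibrate_dab <- function(target, model = stain_model(hdab_vectors()),
                          d_max = 10) {
  if (!is.finite(target) || target < 0) {
    stop("`target` must be a finite non-negative intensity", call. = FALSE)
  }
  if (target == 0) return(0)
  fmax <- dab_response(d_max, model)
  if (target >= fmax) {
    stop(sprintf(
      "target intensity %.3f is not attainable; maximum reachable is %.3f",
      target, fmax
    ), call. = FALSE)
  }
  stats::uniroot(function(d) dab_response(d, model) - target,
                 interval = c(0, d_max), tol = 1e-12)$root
}

# Noiseless end-to-end response of the *actual* measurement chain (eps offset,
# hematoxylin counterstain, unmixing, re-rendering, grayscale, inversion),
# without 8-bit rounding. Used to calibrate phantom density fields so that
# the measured means land on target despite the eps nonlinearity.
pipeline_response <- function(d, model = stain_model(hdab_vectors()),
                              hema = 0.3, eps = 1, i0 = 255,
                              weights = c(1, 1, 1) / 3) {
  vH <- model$matrix["hematoxylin", ]
  vD <- model$matrix["dab", ]
  i0 <- rep_len(i0, 3)
  n <- length(d)
  od_true <- outer(d, vD) + matrix(hema * vH, n, 3, byrow = TRUE)
  intensity <- matrix(i0, n, 3, byrow = TRUE) * 10^(-od_true)
  od_meas <- -log10(sweep(intensity + eps, 2, i0 + eps, "/"))
  od_meas[od_meas < 0] <- 0
  dens <- pmax(od_meas %*% model$unmix[, "dab"], 0)
  rendered <- matrix(i0, n, 3, byrow = TRUE) * 10^(-outer(as.vector(dens), vD))
  255 - as.vector(rendered %*% weights)
}

# Smooth mid-frequency Gaussian texture: coarse white-noise grid, bilinearly
# upsampled. Consumes the current RNG stream.
texture_field <- function(height, width, cell = 16) {
  nr <- ceiling(height / cell) + 2L
  nc <- ceiling(width / cell) + 2L
  g <- matrix(stats::rnorm(nr * nc), nr, nc)
  y <- (seq_len(height) - 0.5) / cell
  x <- (seq_len(width) - 0.5) / cell
  iy <- pmin(floor(y), nr - 2L)
  ix <- pmin(floor(x), nc - 2L)
  fy <- y - iy
  fx <- x - ix
  A <- g[iy + 1, ix + 1, drop = FALSE]
  B <- g[iy + 1, ix + 2, drop = FALSE]
  C <- g[iy + 2, ix + 1, drop = FALSE]
  D <- g[iy + 2, ix + 2, drop = FALSE]
  wy <- matrix(fy, height, width)
  wx <- matrix(fx, height, width, byrow = TRUE)
  (1 - wy) * (1 - wx) * A + (1 - wy) * wx * B + wy * (1 - wx) * C + wy * wx * D
}

# Seeded circular fat-vacuole mask inside the background region; disc centers
# and radii are drawn until the requested pixel fraction is tissue-free.
make_vacuoles <- function(bg_mask, fraction, r_range = c(3, 7)) {
  vac <- matrix(FALSE, nrow(bg_mask), ncol(bg_mask))
  if (fraction <= 0) return(vac)
  idx <- which(bg_mask)
  target <- round(fraction * length(idx))
  h <- nrow(bg_mask)
  count <- 0L
  iter <- 0L
  while (count < target && iter < 5000L) {
    iter <- iter + 1L
    center <- idx[sample.int(length(idx), 1L)]
    r <- stats::runif(1, r_range[1], r_range[2])
    cy <- ((center - 1L) %% h) + 1L
    cx <- ((center - 1L) %/% h) + 1L
    ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(ncol(bg_mask), ceiling(cx + r))
    disc <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    add <- disc & bg_mask[ys, xs, drop = FALSE]
    count <- count + sum(add & !vac[ys, xs, drop = FALSE])
    vac[ys, xs] <- vac[ys, xs, drop = FALSE] | add
  }
  vac
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Elliptical tumor plus split-annulus background geometry
#'
#' The default phantom layout: a central elliptical tumor, an elliptical
#' annulus of adjacent healthy tissue around it, and an unannotated border
#' band between them standing in for the pathologist's tumor-border line.
#' The annulus is encoded as two half-annulus polygons (upper and lower), so
#' every ring is simple (no holes needed).
#'
#' @param height,width Canvas size in pixels.
#' @param border Width of the unannotated band between tumor and background
#'   (default 10 px).
#' @param arc_steps Vertices per half arc (default 36).
#' @return A [roi_set()] with one tumor and two background polygons.
#' @export
default_geometry <- function(height, width, border = 10, arc_steps = 36) {
  cx <- width / 2
  cy <- height / 2
  a <- 0.30 * width
  b <- 0.24 * height
  inner_a <- a + border
  inner_b <- b + border
  ring <- min(0.10 * min(height, width), min(cx, cy) - 2 - max(inner_a, inner_b))
  if (ring < 4) stop("canvas too small for the default geometry", call. = FALSE)
  outer_a <- inner_a + ring
  outer_b <- inner_b + ring

  ellipse_arc <- function(ea, eb, from, to, n) {
    th <- seq(from, to, length.out = n)
    cbind(cx + ea * cos(th), cy + eb * sin(th))
  }
  tumor <- ellipse_arc(a, b, 0, 2 * pi * (1 - 1 / (4 * arc_steps)), 4 * arc_steps)
  upper <- rbind(
    ellipse_arc(outer_a, outer_b, 0, pi, arc_steps + 1),
    ellipse_arc(inner_a, inner_b, pi, 0, arc_steps + 1)
  )
  lower <- rbind(
    ellipse_arc(outer_a, outer_b, pi, 2 * pi, arc_steps + 1),
    ellipse_arc(inner_a, inner_b, 2 * pi, pi, arc_steps + 1)
  )
  roi_set(
    labels = c("tumor", "background", "background"),
    polygons = list(tumor, upper, lower)
  )
}

#' Specify a synthetic H-DAB phantom
#'
#' A phantom is a Beer-Lambert forward model: hematoxylin counterstain
#' everywhere, region-dependent DAB density (optionally modulated by a
#' seeded mid-frequency texture field), Gaussian pixel noise in OD space,
#' and white tissue-free fat vacuoles punched into the background.
#'
#' @param height,width Canvas size.
#' @param roiset Tumor/background geometry ([roi_set()]); defaults to
#'   [default_geometry()]. May be pre-rasterized.
#' @param hematoxylin_density Counterstain OD density everywhere (>= 0).
#' @param dab_density_tumor,dab_density_background Base DAB densities.
#' @param texture_amp_tumor,texture_amp_background Density amplitude of the
#'   standardized texture field per region (0 disables texture).
#' @param pixel_noise_sd Gaussian OD-space noise SD per channel.
#' @param vacuole_fraction Fraction of background pixels replaced by white
#'   vacuoles, in \[0, 0.3\].
#' @param seed Integer seed; regenerating from an identical spec reproduces
#'   the slide bit for bit.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(height, width, roiset = NULL,
                         hematoxylin_density = 0.3,
                         dab_density_tumor = 0.3,
                         dab_density_background = 0.1,
                         texture_amp_tumor = 0,
                         texture_amp_background = 0,
                         pixel_noise_sd = 0.03,
                         vacuole_fraction = 0.08,
                         texture_cell = 16,
                         seed = 1L) {
  if (height < 8 || width < 8) stop("canvas must be at least 8x8", call. = FALSE)
  if (is.null(roiset)) roiset <- default_geometry(height, width)
  vals <- c(hematoxylin_density, dab_density_tumor, dab_density_background,
            texture_amp_tumor, texture_amp_background, pixel_noise_sd)
  if (any(!is.finite(vals))) stop("phantom densities must be finite", call. = FALSE)
  if (hematoxylin_density < 0 || pixel_noise_sd < 0) {
    stop("hematoxylin density and noise SD must be non-negative", call. = FALSE)
  }
  if (texture_amp_tumor == 0 && dab_density_tumor < 0 ||
      texture_amp_background == 0 && dab_density_background < 0) {
    stop("base DAB densities must be non-negative", call. = FALSE)
  }
  if (vacuole_fraction < 0 || vacuole_fraction > 0.3) {
    stop("`vacuole_fraction` must lie in [0, 0.3]", call. = FALSE)
  }
  structure(
    list(
      height = height, width = width, roiset = roiset,
      hematoxylin_density = hematoxylin_density,
      dab_density_tumor = dab_density_tumor,
      dab_density_background = dab_density_background,
      texture_amp_tumor = texture_amp_tumor,
      texture_amp_background = texture_amp_background,
      pixel_noise_sd = pixel_noise_sd,
      vacuole_fraction = vacuole_fraction,
      texture_cell = texture_cell,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Seeded deterministic part of the phantom: rasterized ROIs, texture field,
# vacuole mask. The RNG is seeded here and left positioned for the noise
# draw, so calibration and generation see identical fields.
phantom_fields <- function(spec) {
  roiset <- spec$roiset
  if (is.null(roiset$masks)) {
    roiset <- rasterize_rois(roiset, spec$height, spec$width)
  }
  set.seed(spec$seed)
  tex <- texture_field(spec$height, spec$width, spec$texture_cell)
  vac <- make_vacuoles(roiset$masks$background, spec$vacuole_fraction)
  list(roiset = roiset, texture = tex, vacuoles = vac)
}

#' Generate a synthetic slide from a phantom spec
#'
#' Per pixel OD is `hematoxylin_density * v_H + D(x) * v_DAB` plus seeded
#' Gaussian OD noise per channel; intensity is `255 * 10^(-OD)` quantized to
#' 8 bits; vacuole pixels are forced to blank glass. The pre-noise density
#' fields are kept as ground truth.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `synthetic_slide`: `image` (H x W x 3, 0-255),
#'   `roiset` (rasterized), `truth` (list of `hematoxylin` and `dab` density
#'   matrices plus the vacuole mask), `spec`.
#' @export
forward_model <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fields <- phantom_fields(spec)
  roiset <- fields$roiset
  h <- spec$height
  w <- spec$width
  m_t <- roiset$masks$tumor
  m_b <- roiset$masks$background
  m_bt <- m_b & !fields$vacuoles

  D <- matrix(max(spec$dab_density_background, 0), h, w)
  if (spec$texture_amp_background > 0 && any(m_bt)) {
    D[m_bt] <- pmax(spec$dab_density_background +
                      spec$texture_amp_background * standardize(fields$texture[m_bt]), 0)
  }
  D[m_t] <- if (spec$texture_amp_tumor > 0) {
    pmax(spec$dab_density_tumor +
           spec$texture_amp_tumor * standardize(fields$texture[m_t]), 0)
  } else {
    max(spec$dab_density_tumor, 0)
  }

  hema <- matrix(spec$hematoxylin_density, h, w)
  model <- stain_model(hdab_vectors())
  vH <- model$matrix["hematoxylin", ]
  vD <- model$matrix["dab", ]
  img <- array(0, dim = c(h, w, 3))
  for (c in 1:3) {
    od <- hema * vH[c] + D * vD[c]
    if (spec$pixel_noise_sd > 0) {
      od <- od + matrix(stats::rnorm(h * w, sd = spec$pixel_noise_sd), h, w)
    }
    img[, , c] <- pmin(pmax(round(255 * 10^(-od)), 0), 255)
  }
  if (any(fields$vacuoles)) {
    for (c in 1:3) {
      ch <- img[, , c]
      ch[fields$vacuoles] <- 255
      img[, , c] <- ch
    }
  }
  structure(
    list(
      image = img, roiset = roiset,
      truth = list(hematoxylin = hema, dab = D, vacuoles = fields$vacuoles),
      spec = spec
    ),
    class = "synthetic_slide"
  )
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %dx%d, tumor DAB %.3f, background DAB %.3f, noise SD %.3f\n",
              x$spec$height, x$spec$width, x$spec$dab_density_tumor,
              x$spec$dab_density_background, x$spec$pixel_noise_sd))
  invisible(x)
}

# Joint calibration of (base density, texture amplitude) for one region so
# the noiseless measured intensity distribution hits a target mean and SD.
# `tvals` are the standardized texture values on the region's pixels
# (possibly quantile-compressed); response is the monotone density ->
# intensity map. The base density is solved by bracketed root-finding at
# each candidate amplitude; the amplitude is then solved against the SD.
calibrate_region <- function(target_mean, target_sd, tvals, response,
                             a_max = 1.5) {
  mean_at <- function(d0, a) mean(response(pmax(d0 + a * tvals, 0)))
  solve_d0 <- function(a) {
    lo <- -a * max(abs(tvals), 1e-9) - 0.01
    stats::uniroot(function(d0) mean_at(d0, a) - target_mean,
                   interval = c(lo, 8), tol = 1e-8)$root
  }
  if (target_sd <= 0) return(list(d0 = solve_d0(0), a = 0))
  sd_gap <- function(a) {
    d0 <- solve_d0(a)
    stats::sd(response(pmax(d0 + a * tvals, 0))) - target_sd
  }
  a <- if (sd_gap(a_max) <= 0) a_max else {
    stats::uniroot(sd_gap, interval = c(1e-6, a_max), tol = 1e-5)$root
  }
  list(d0 = solve_d0(a), a = a)
}

compress_quantiles <- function(x, k = 1024) {
  stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE, type = 7)
}
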