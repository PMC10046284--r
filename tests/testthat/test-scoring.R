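test_that("grayscale conversion applies the channel weights", {
  px <- array(c(30, 60, 90), dim = c(1, 1, 3))
  expect_equal(as.vector(to_grayscale(px)), 60)
  expect_equal(as.vector(to_grayscale(px, c(0.299, 0.587, 0.114))), 54.45)

  white <- array(255, dim = c(3, 4, 3))
  expect_true(all(to_grayscale(white) == 255))

  expect_error(to_grayscale(px, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("inversion flips the 0-255 scale once and only once", {
  g <- to_grayscale(array(c(0, 255, 100), dim = c(1, 3, 3)))
  inv <- invert_gray(g)
  expect_equal(as.vector(inv), c(255, 0, 155))
  expect_equal(mean(inv), 255 - mean(g))
  expect_error(invert_gray(inv), "already inverted")
})

test_that("ROI measurement returns mean, sample SD and pixel count", {
  g <- matrix(100, 4, 4)
  attr(g, "inverted") <- TRUE
  mask <- matrix(TRUE, 4, 4)
  st <- measure_roi(g, mask)
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
  expect_equal(st$n_pixels, 16)

  g2 <- matrix(c(10, 20, 0, 0), 2, 2)
  attr(g2, "inverted") <- TRUE
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  st2 <- measure_roi(g2, m2)
  expect_equal(st2$mean, 15)
  expect_equal(st2$sd, sqrt(sum((c(10, 20) - 15)^2) / 1), tolerance = 1e-12)

  # full-image mask agrees with the raster-wide statistics
  set.seed(3)
  g3 <- matrix(runif(30, 0, 255), 5, 6)
  attr(g3, "inverted") <- TRUE
  st3 <- measure_roi(g3, matrix(TRUE, 5, 6))
  expect_equal(st3$mean, mean(g3))

  expect_error(measure_roi(g3, matrix(FALSE, 5, 6)), "empty")
  expect_warning(
    one <- measure_roi(g3, matrix(c(TRUE, rep(FALSE, 29)), 5, 6)),
    "single-pixel"
  )
  expect_equal(one$sd, 0)
  g_raw <- matrix(1, 2, 2)
  expect_error(measure_roi(g_raw, matrix(TRUE, 2, 2)), "inverted")
})

test_that("TBR is the ratio of mean intensities, with guarded edge cases", {
  expect_equal(compute_tbr(list(mean = 50), list(mean = 50)), 1)
  expect_equal(compute_tbr(list(mean = 90), list(mean = 45)), 2)
  expect_equal(compute_tbr(list(mean = 81), list(mean = 81 / 3.1)), 3.1)
  expect_message(tbr <- compute_tbr(list(mean = 40), list(mean = 50)), "< 1")
  expect_equal(tbr, 0.8)
  expect_error(compute_tbr(list(mean = 10), list(mean = 0)), "undefined")
})

test_that("score_slide matches the closed-form response on noiseless phantoms", {
  d_t <- 0.45; d_b <- 0.12
  slide <- forward_model(flat_phantom(d_t, d_b, h = 24, w = 24))
  # eps is negligible here so the simple closed form is the oracle
  sc <- score_slide(slide$image, slide$roiset,
                    cfg = scoring_config(eps = 1e-9),
                    sample_id = "phantom", biomarker = "X")
  expect_equal(sc$tumor_mean, dab_response(d_t), tolerance = 2 / dab_response(d_t))
  expect_equal(sc$bg_mean, dab_response(d_b), tolerance = 2 / dab_response(d_b))
  expect_equal(sc$tbr, dab_response(d_t) / dab_response(d_b), tolerance = 0.05)
  expect_false(sc$tbr_below_1)
})

test_that("equal tumor and background density gives TBR 1 up to quantization", {
  slide <- forward_model(flat_phantom(0.3, 0.3, h = 20, w = 20))
  sc <- score_slide(slide$image, slide$roiset)
  expect_equal(sc$tbr, 1, tolerance = 0.02)
})

test_that("hematoxylin-only slides leak at most 2 gray levels into DAB", {
  slide <- forward_model(flat_phantom(0, 0, h = 20, w = 20, hema = 0.8))
  m <- stain_model(hdab_vectors())
  dab <- deconvolve(rgb_to_od(slide$image), m)[, , "dab"]
  inv <- invert_gray(to_grayscale(render_stain(dab, m$matrix["dab", ])))
  tumor <- measure_roi(inv, slide$roiset$masks$tumor)
  bg <- measure_roi(inv, slide$roiset$masks$background)
  expect_lt(tumor$mean, 2)
  expect_lt(bg$mean, 2)
  # an all-zero DAB slide has no defined TBR
  expect_error(score_slide(slide$image, slide$roiset), "step 5.*undefined")
})

test_that("tumor mean increases strictly with ground-truth DAB density", {
  means <- vapply(c(0.1, 0.2, 0.35, 0.5, 0.8), function(d) {
    slide <- forward_model(flat_phantom(d, 0.1, h = 20, w = 20,
                                        noise = 0.03, seed = 5))
    score_slide(slide$image, slide$roiset)$tumor_mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("swapping ROI labels inverts the TBR", {
  slide <- forward_model(flat_phantom(0.5, 0.15, h = 20, w = 20))
  swapped <- roi_set(
    labels = c("background", "tumor", "tumor")[
      match(slide$roiset$rois$label, c("tumor", "background", "background"))],
    polygons = slide$roiset$rois$vertices
  )
  sc <- score_slide(slide$image, slide$roiset)
  sc_sw <- suppressMessages(score_slide(slide$image, swapped))
  expect_equal(sc_sw$tbr, 1 / sc$tbr, tolerance = 1e-9)
  expect_true(sc_sw$tbr_below_1)
})

test_that("stage failures are tagged with their protocol step", {
  slide <- forward_model(flat_phantom(0.3, 0.1, h = 12, w = 12))
  bad_cfg <- scoring_config(grayscale_weights = c(0.5, 0.5, 0.5))
  expect_error(score_slide(slide$image, slide$roiset, cfg = bad_cfg),
               "step 3")
})

test_that("gradient maps span the colormap and flag degenerate ranges", {
  g <- matrix(seq(0, 90, length.out = 9), 3, 3)
  gm <- gradient_map(g)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))
  expect_equal(as.vector(gm[1, 1, ]), as.vector(pal[, 1]), tolerance = 1)
  expect_equal(as.vector(gm[3, 3, ]), as.vector(pal[, 256]), tolerance = 1)
  expect_equal(attr(gm, "scale_min"), 0)
  expect_equal(attr(gm, "scale_max"), 90)
  # order preservation: distinct increasing values map to distinct colors
  cols <- apply(matrix(gm, ncol = 3), 1, paste, collapse = ",")
  expect_equal(length(unique(cols)), 9)

  expect_warning(flat <- gradient_map(matrix(5, 2, 2)), "degenerate")
  mid <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))[, 128]
  expect_lt(max(abs(flat[1, 1, ] - mid)), 3)
})
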