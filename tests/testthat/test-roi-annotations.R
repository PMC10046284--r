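test_that("GeoJSON annotations read back with validated labels", {
  path <- write_square_annotation()
  rs <- read_annotations(path)
  expect_s3_class(rs, "roi_set")
  expect_equal(sort(rs$rois$label), c("background", "tumor"))
  expect_equal(nrow(rs$rois$vertices[[1]]), 4)  # closing vertex dropped

  bad <- write_square_annotation(labels = c("tumor", "stroma"))
  expect_error(read_annotations(bad), "feature 2.*stroma")
})

test_that("multiple polygons may share a label; holes are rejected", {
  path <- tempfile(fileext = ".geojson")
  sq <- function(x0, y0) list(c(x0, y0), c(x0 + 2, y0), c(x0 + 2, y0 + 2),
                              c(x0, y0 + 2), c(x0, y0))
  feats <- list(
    list(type = "Feature", properties = list(label = "tumor"),
         geometry = list(type = "Polygon", coordinates = list(sq(0, 0)))),
    list(type = "Feature", properties = list(label = "tumor"),
         geometry = list(type = "Polygon", coordinates = list(sq(4, 0)))),
    list(type = "Feature", properties = list(label = "background"),
         geometry = list(type = "Polygon", coordinates = list(sq(8, 0))))
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  rs <- read_annotations(path)
  expect_equal(sum(rs$rois$label == "tumor"), 2)
  expect_equal(nrow(rs$rois), 3)

  holey <- list(list(
    type = "Feature", properties = list(label = "tumor"),
    geometry = list(type = "Polygon", coordinates = list(sq(0, 0), sq(1, 1)))
  ))
  jsonlite::write_json(list(type = "FeatureCollection", features = holey),
                       path, auto_unbox = TRUE, digits = NA)
  expect_error(read_annotations(path), "holes")
})

test_that("write_annotations / read_annotations round trip", {
  rs <- square_roiset()
  path <- tempfile(fileext = ".geojson")
  write_annotations(rs, path)
  back <- read_annotations(path)
  expect_equal(back$rois$label, rs$rois$label)
  expect_equal(back$rois$vertices, rs$rois$vertices)
})

test_that("rasterization follows the pixel-center even-odd rule", {
  full <- roi_set(
    c("tumor", "background"),
    list(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)),   # covers a full 2x2 tile
         cbind(c(3, 4, 4, 3), c(0, 0, 2, 2)))
  )
  m <- rasterize_rois(full, 2, 6)
  expect_equal(sum(m$masks$tumor), 4)

  half <- roi_set(
    c("tumor", "background"),
    list(cbind(c(0, 1, 1, 0), c(0, 0, 2, 2)),   # x in [0,1): one column
         cbind(c(3, 4, 4, 3), c(0, 0, 2, 2)))
  )
  mh <- rasterize_rois(half, 2, 6)
  expect_equal(sum(mh$masks$tumor), 2)
  expect_true(all(which(mh$masks$tumor) %in% c(1, 2)))
})

test_that("disc and annulus masks match an independent point-in-polygon oracle", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  disc <- cbind(5 + 3 * cos(th), 5 + 3 * sin(th))
  ann_out <- cbind(5 + 4.8 * cos(th), 5 + 4.8 * sin(th))
  ann_in <- cbind(5 + 3.5 * cos(rev(th)), 5 + 3.5 * sin(rev(th)))
  upper <- rbind(ann_out[1:13, ], ann_in[12:24, ])
  lower <- rbind(ann_out[13:24, ], ann_out[1, , drop = FALSE],
                 ann_in[c(24, 1:12), ])
  rs <- rasterize_rois(
    roi_set(c("tumor", "background", "background"),
            list(disc, upper, lower)), 10, 10
  )
  centers <- expand.grid(y = seq_len(10) - 0.5, x = seq_len(10) - 0.5)
  oracle_disc <- mgcv::in.out(rbind(disc, disc[1, ]),
                              cbind(centers$x, centers$y))
  expect_equal(as.vector(rs$masks$tumor), oracle_disc)
  oracle_ann <- mgcv::in.out(rbind(ann_out, ann_out[1, ]),
                             cbind(centers$x, centers$y)) & !
    mgcv::in.out(rbind(ann_in, ann_in[1, ]), cbind(centers$x, centers$y))
  expect_equal(as.vector(rs$masks$background), oracle_ann)
  expect_equal(sum(rs$masks$tumor & rs$masks$background), 0)
})

test_that("rasterized area of convex polygons is within a perimeter band", {
  set.seed(11)
  for (i in 1:8) {
    w <- runif(1, 3, 20); h <- runif(1, 3, 20)
    x0 <- runif(1, 1, 10); y0 <- runif(1, 1, 10)
    rect <- cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
    m <- rasterize_polygon(rect, 40, 40)
    area <- w * h
    perim <- 2 * (w + h)
    expect_lt(abs(sum(m) - area), perim)
  }
})

test_that("rasterization is independent of vertex start index and orientation", {
  v <- cbind(c(1, 6, 7, 3), c(1, 2, 6, 5))
  base <- rasterize_polygon(v, 9, 9)
  expect_identical(rasterize_polygon(v[c(3, 4, 1, 2), ], 9, 9), base)
  expect_identical(rasterize_polygon(v[4:1, ], 9, 9), base)
  # idempotence of the full ROI-set rasterization
  rs <- rasterize_rois(square_roiset(), 12, 12)
  rs2 <- rasterize_rois(rs, 12, 12)
  expect_identical(rs2$masks, rs$masks)
})

test_that("overlapping and out-of-image ROIs raise dedicated errors", {
  overlap <- roi_set(
    c("tumor", "background"),
    list(cbind(c(0, 6, 6, 0), c(0, 0, 6, 6)),
         cbind(c(4, 10, 10, 4), c(0, 0, 6, 6)))
  )
  expect_error(rasterize_rois(overlap, 8, 12), "overlap on [0-9]+ pixels")

  outside <- roi_set(
    c("tumor", "background"),
    list(cbind(c(1, 3, 3, 1), c(1, 1, 3, 3)),
         cbind(c(50, 60, 60, 50), c(1, 1, 3, 3)))
  )
  expect_error(rasterize_rois(outside, 8, 8), "'background' mask is empty")
})

test_that("degenerate polygons are rejected at construction", {
  expect_error(
    roi_set("tumor", list(cbind(c(0, 1), c(0, 1)))),
    "at least one 'background'"
  )
  expect_error(
    roi_set(c("tumor", "background"),
            list(cbind(c(0, 1), c(0, 1)), cbind(c(2, 3, 3), c(0, 0, 1)))),
    "at least 3 vertices"
  )
  bowtie <- cbind(c(0, 4, 0, 4), c(0, 4, 4, 0))
  expect_error(
    roi_set(c("tumor", "background"),
            list(bowtie, cbind(c(6, 8, 8), c(0, 0, 2)))),
    "self-intersecting"
  )
})
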