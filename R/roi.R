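#' Read pathologist-style polygon annotations
#'
#' Parses a GeoJSON FeatureCollection of polygon features carrying a `label`
#' property (`"tumor"` or `"background"`). Coordinates are image pixel
#' coordinates: origin at the top-left corner, x rightward, y downward; any
#' CRS member is ignored. Multiple polygons may share a label (they are
#' unioned at rasterization). Interior rings (holes) are not supported.
#'
#' @param file Path to a GeoJSON file.
#' @return An object of class `roi_set`: list with `rois` (tibble of
#'   `label` and `vertices`, each a two-column matrix), and unset `masks`.
#' @export
read_annotations <- function(file) {
  gj <- jsonlite::read_json(file)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("annotation file must be a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  if (length(feats) == 0) stop("annotation file has no features", call. = FALSE)
  rois <- purrr::imap(feats, function(f, i) {
    label <- f$properties$label
    if (is.null(label) || !label %in% c("tumor", "background")) {
      stop(sprintf(
        "feature %d: label %s is not one of 'tumor', 'background'",
        i, if (is.null(label)) "<missing>" else sQuote(label)
      ), call. = FALSE)
    }
    geom <- f$geometry
    if (is.null(geom$type) || geom$type != "Polygon") {
      stop(sprintf("feature %d: geometry must be a Polygon", i), call. = FALSE)
    }
    rings <- geom$coordinates
    if (length(rings) > 1) {
      stop(sprintf("feature %d: polygons with interior rings (holes) are not supported",
                   i), call. = FALSE)
    }
    v <- do.call(rbind, lapply(rings[[1]], function(p) as.numeric(unlist(p))))
    # RFC 7946 rings repeat the first vertex; store the open ring
    if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    if (nrow(v) < 3) {
      stop(sprintf("feature %d: polygon needs at least 3 vertices", i),
           call. = FALSE)
    }
    list(label = label, vertices = v)
  })
  roi_set(
    labels = purrr::map_chr(rois, "label"),
    polygons = purrr::map(rois, "vertices")
  )
}

#' Construct an ROI set from labeled polygons
#'
#' @param labels Character vector, one of `"tumor"`, `"background"` per polygon.
#' @param polygons List of two-column vertex matrices (x, y), pixel units.
#' @return `roi_set` object (masks unset until [rasterize_rois()]).
#' @export
roi_set <- function(labels, polygons) {
  stopifnot(length(labels) == length(polygons))
  if (!all(labels %in% c("tumor", "background"))) {
    stop("ROI labels must be 'tumor' or 'background'", call. = FALSE)
  }
  for (lab in c("tumor", "background")) {
    if (!lab %in% labels) {
      stop(sprintf("ROI set must contain at least one '%s' polygon", lab),
           call. = FALSE)
    }
  }
  polygons <- lapply(polygons, function(v) {
    v <- as.matrix(v)
    if (nrow(v) < 3) stop("polygons need at least 3 vertices", call. = FALSE)
    if (polygon_self_intersects(v)) {
      stop("polygon is self-intersecting", call. = FALSE)
    }
    unname(v)
  })
  structure(
    list(
      rois = tibble::tibble(label = labels, vertices = polygons),
      masks = NULL, height = NA_integer_, width = NA_integer_
    ),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>", nrow(x$rois), "polygons (",
      sum(x$rois$label == "tumor"), "tumor /",
      sum(x$rois$label == "background"), "background )\n")
  if (!is.null(x$masks)) {
    cat("  rasterized", x$height, "x", x$width, ": tumor",
        sum(x$masks$tumor), "px, background", sum(x$masks$background), "px\n")
  }
  invisible(x)
}

# O(n^2) segment-pair test, ignoring adjacent edges; polygons here are small
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      o1 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      o2 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      o3 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      o4 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (o1 != o2 && o3 != o4 && all(c(o1, o2, o3, o4) != 0)) return(TRUE)
    }
  }
  FALSE
}

# Even-odd (ray casting) fill over pixel centers for one polygon, restricted
# to the image grid. Returns an H x W logical matrix. A pixel (row r, col c,
# both 1-based) has center (c - 0.5, r - 0.5) in annotation coordinates.
rasterize_polygon <- function(vertices, height, width) {
  mask <- matrix(FALSE, height, width)
  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  n <- nrow(vertices)
  jx <- vertices[c(n, 1:(n - 1)), 1]; jy <- vertices[c(n, 1:(n - 1)), 2]
  ix <- vertices[, 1]; iy <- vertices[, 2]
  for (e in seq_len(n)) {
    y1 <- iy[e]; y2 <- jy[e]
    if (y1 == y2) next
    rows <- which((ys >= min(y1, y2)) & (ys < max(y1, y2)))
    # half-open edge span in y gives the standard crossing-parity rule
    rows <- rows[(y1 > ys[rows]) != (y2 > ys[rows])]
    if (length(rows) == 0) next
    xint <- ix[e] + (ys[rows] - y1) * (jx[e] - ix[e]) / (y2 - y1)
    flip <- outer(xint, xs, FUN = ">")
    mask[rows, ] <- xor(mask[rows, , drop = FALSE], flip)
  }
  mask
}

#' Rasterize an ROI set to tumor and background masks
#'
#' A pixel belongs to a region iff its center lies inside the union of that
#' label's polygons under the even-odd rule (0-based pixel indices, center at
#' `(x + 0.5, y + 0.5)`). Tumor and background masks must come out disjoint
#' and non-empty.
#'
#' @param roiset A [roi_set()].
#' @param height,width Image dimensions in pixels.
#' @return The `roi_set` with `masks` set (`list(tumor =, background =)`,
#'   logical H x W matrices).
#' @export
rasterize_rois <- function(roiset, height, width) {
  stopifnot(inherits(roiset, "roi_set"))
  if (height < 1 || width < 1) stop("image dimensions must be positive", call. = FALSE)
  masks <- list()
  for (lab in c("tumor", "background")) {
    polys <- roiset$rois$vertices[roiset$rois$label == lab]
    m <- matrix(FALSE, height, width)
    for (v in polys) m <- m | rasterize_polygon(v, height, width)
    if (!any(m)) {
      stop(sprintf("'%s' mask is empty within the %dx%d image", lab, height, width),
           call. = FALSE)
    }
    masks[[lab]] <- m
  }
  overlap <- sum(masks$tumor & masks$background)
  if (overlap > 0) {
    stop(sprintf("tumor and background ROIs overlap on %d pixels", overlap),
         call. = FALSE)
  }
  roiset$masks <- masks
  roiset$height <- as.integer(height)
  roiset$width <- as.integer(width)
  roiset
}

#' Write an ROI set as GeoJSON
#'
#' Inverse of [read_annotations()]; one Feature per polygon, closed rings,
#' image pixel coordinates.
#'
#' @param roiset A [roi_set()].
#' @param file Output path.
#' @export
write_annotations <- function(roiset, file) {
  stopifnot(inherits(roiset, "roi_set"))
  feats <- purrr::map2(roiset$rois$label, roiset$rois$vertices, function(lab, v) {
    ring <- rbind(v, v[1, , drop = FALSE])
    coords <- lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
    list(
      type = "Feature",
      properties = list(label = lab),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' Export a rasterized mask as a 0/255 PNG
#'
#' @param roiset Rasterized [roi_set()].
#' @param label `"tumor"` or `"background"`.
#' @param file Output PNG path.
#' @export
write_mask_png <- function(roiset, label, file) {
  if (is.null(roiset$masks)) stop("masks not set; call rasterize_rois() first",
                                  call. = FALSE)
  png::writePNG(roiset$masks[[label]] * 1.0, file)
  invisible(file)
}
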