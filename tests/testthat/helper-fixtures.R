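# Shared fixture builders; everything is generated in code at test time.

hdab_model <- stain_model(hdab_vectors())

# Square tumor / square background annotation, disjoint, inside an h x w tile
square_roiset <- function(h = 12, w = 12) {
  roi_set(
    labels = c("tumor", "background"),
    polygons = list(
      cbind(c(1, 5, 5, 1), c(1, 1, 5, 5)),
      cbind(c(7, 11, 11, 7), c(1, 1, 5, 5))
    )
  )
}

# Noiseless flat phantom with given DAB densities on the square geometry
flat_phantom <- function(d_tumor, d_bg, h = 12, w = 12, hema = 0.3,
                         noise = 0, vac = 0, seed = 1) {
  phantom_spec(
    h, w, roiset = square_roiset(h, w), hematoxylin_density = hema,
    dab_density_tumor = d_tumor, dab_density_background = d_bg,
    pixel_noise_sd = noise, vacuole_fraction = vac, seed = seed
  )
}

# GeoJSON fixture written to a temp file
write_square_annotation <- function(path = tempfile(fileext = ".geojson"),
                                    labels = c("tumor", "background")) {
  features <- list(
    list(type = "Feature", properties = list(label = labels[1]),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(1, 1), c(5, 1), c(5, 5), c(1, 5), c(1, 1))))),
    list(type = "Feature", properties = list(label = labels[2]),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(7, 1), c(11, 1), c(11, 5), c(7, 5), c(7, 1)))))
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# Brute-force reference t statistics written as explicit sums
brute_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  t <- md / (sd_d / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

brute_unpaired_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  s1 <- sum((a - m1)^2); s2 <- sum((b - m2)^2)
  sp2 <- (s1 + s2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n1 + n2 - 2))
}
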