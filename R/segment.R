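#' Vegetative greenness image (ExG - ExR)
#'
#' Per pixel, excess green `ExG = 2G - R - B` and excess red
#' `ExR = 1.4R - B` are combined into the vegetative greenness
#' `G_V = ExG - ExR`, clipped to the 0--255 display range. Leaf pixels score
#' high, soil and red markers score 0.
#'
#' @param img a [calibrated_image()] (or any [tray_image()]).
#' @return A `greenness_image`: list with `values` (`H x W` matrix in
#'   `[0, 255]`) and `clip_range`.
#' @export
compute_greenness_img <- function(img) {
  px <- img$pixels
  gv <- 2 * px[, , 2] - px[, , 1] - px[, , 3] - (1.4 * px[, , 1] - px[, , 3])
  structure(list(values = pmax(pmin(gv, 255), 0), clip_range = c(0, 255)),
            class = "greenness_image")
}

#' @export
print.greenness_image <- function(x, ...) {
  cat(sprintf("<greenness_image> %d x %d, range [%.1f, %.1f]\n",
              nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Pick the midpoint sample image of a series
#'
#' The colour-group count of a series is estimated from one representative
#' image: the midpoint, i.e. the element at 1-based index
#' `floor((n + 1) / 2)` (the 5th image of a 10-image series).
#'
#' @param series a list (or vector) of images/paths.
#' @return The midpoint element.
#' @export
select_sample_image <- function(series) {
  n <- length(series)
  if (n < 1L) stop("empty image series")
  series[[(n + 1L) %/% 2L]]
}

#' Clustering configuration
#'
#' @param k colour-group count, or `NULL` to estimate it from the sample
#'   image. User-supplied values are clamped to `[k_min, k_max]`.
#' @param k_min,k_max accepted range of `k` (3--10).
#' @param probe_k number of probe clusters used when estimating `k`.
#' @param max_pixels subsample cap for clustering.
#' @param seed fixed RNG seed used for every k-means call, so results are
#'   reproducible and independent of scheduling.
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(k = NULL, k_min = 3L, k_max = 10L,
                              probe_k = 8L, max_pixels = 50000L,
                              seed = 42L) {
  if (!is.null(k)) k <- min(max(as.integer(k), k_min), k_max)
  structure(list(k = k, k_min = k_min, k_max = k_max, probe_k = probe_k,
                 max_pixels = max_pixels, seed = seed),
            class = "clustering_config")
}

# Run a deterministic k-means without disturbing the caller's RNG stream.
seeded_kmeans <- function(x, centers, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  suppressWarnings(stats::kmeans(x, centers = centers, nstart = 3,
                                 iter.max = 50))
}

#' Estimate the number of representative colour groups
#'
#' RGB pixels of the sample image (subsampled) are clustered into
#' `probe_k = 8` probe groups; `k` is the number of clusters whose pixel
#' count reaches the median cluster count, clamped to `[3, 10]`.
#'
#' @param sample a [calibrated_image()] (the series midpoint image).
#' @param cfg a [clustering_config()].
#' @return Integer `k`.
#' @export
estimate_colour_groups <- function(sample, cfg = clustering_config()) {
  px <- sample$pixels
  X <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
             as.vector(px[, , 3]))
  if (nrow(X) > cfg$max_pixels) {
    idx <- round(seq(1, nrow(X), length.out = cfg$max_pixels))
    X <- X[idx, , drop = FALSE]
  }
  n_distinct <- nrow(unique(X))
  pk <- min(cfg$probe_k, n_distinct)
  if (pk < 2L) return(cfg$k_min)
  km <- seeded_kmeans(X, pk, cfg$seed)
  sizes <- km$size
  k <- sum(sizes >= stats::median(sizes))
  min(max(k, cfg$k_min), cfg$k_max)
}

#' Leaf mask from k-means clustering of the greenness image
#'
#' `G_V` values are clustered into `k` groups (1-D k-means on a pixel
#' subsample, all pixels then assigned to the nearest centre); pixels whose
#' cluster mean greenness exceeds the global Otsu level of the `G_V` image
#' form the mask. A constant greenness image yields an empty mask.
#'
#' @param gv a `greenness_image` from [compute_greenness_img()].
#' @param k number of colour groups (3--10).
#' @param cfg a [clustering_config()] (for the subsample cap and seed).
#' @return A `leaf_mask`: list with binary `mask` and `origin = "global"`.
#' @export
kmeans_leaf_mask <- function(gv, k, cfg = clustering_config()) {
  stopifnot(inherits(gv, "greenness_image"))
  if (k < cfg$k_min || k > cfg$k_max)
    stop("'k' must lie in [", cfg$k_min, ", ", cfg$k_max, "]")
  vals <- gv$values
  out <- matrix(0L, nrow(vals), ncol(vals))
  uv <- unique(as.vector(vals))
  if (length(uv) < 2L)
    return(leaf_mask(out, "global"))
  v <- as.vector(vals)
  samp <- if (length(v) > cfg$max_pixels)
    v[round(seq(1, length(v), length.out = cfg$max_pixels))] else v
  k_eff <- min(k, length(unique(samp)))
  km <- seeded_kmeans(matrix(samp, ncol = 1), k_eff, cfg$seed)
  centers <- sort(as.vector(km$centers))
  thr <- otsu_threshold(vals)
  hot <- centers[centers > thr]
  if (length(hot) > 0) {
    # assign each pixel to its nearest centre via the midpoints between
    # consecutive sorted centres
    cuts <- (centers[-1] + centers[-length(centers)]) / 2
    assign <- findInterval(v, cuts) + 1L
    out[matrix(centers[assign] > thr, nrow(vals), ncol(vals))] <- 1L
  }
  leaf_mask(out, "global")
}

#' Leaf mask from Lab colour opponency
#'
#' The image is converted to CIE Lab; on the green--red opponent channel
#' (`a*`, negative towards green) an Otsu threshold separates the green
#' side, and only pixels that are actually green (`a* < -2`) are kept, so a
#' greyscale image yields an empty mask. This route recovers small leaves
#' that the clustering route can miss.
#'
#' @param img a [calibrated_image()] (or [tray_image()]).
#' @return A `leaf_mask` with `origin = "global"`.
#' @export
lab_leaf_mask <- function(img) {
  px <- img$pixels
  a <- rgb_to_lab_a(px[, , 1], px[, , 2], px[, , 3])
  thr <- min(otsu_threshold(a), -2)
  leaf_mask(matrix(as.integer(a < thr), nrow(a)), "global")
}

# Fast sRGB (0-255, D65) -> CIE Lab a* channel. Closed-form standard
# transform (gamma expansion, XYZ matrix, f() cube-root compression);
# validated against grDevices::convertColor in the test suite.
rgb_to_lab_a <- function(r, g, b) {
  lin <- function(u) {
    u <- u / 255
    ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  }
  R <- lin(r); G <- lin(g); B <- lin(b)
  X <- 0.4124564 * R + 0.3575761 * G + 0.1804375 * B
  Y <- 0.2126729 * R + 0.7151522 * G + 0.0721750 * B
  # D65 white point
  fx <- lab_f(X / 0.95047)
  fy <- lab_f(Y)
  500 * (fx - fy)
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' Binary leaf mask
#'
#' @param mask `H x W` binary (0/1) matrix.
#' @param origin `"global"` (image level) or `"pot"`.
#' @return A `leaf_mask` object.
#' @export
leaf_mask <- function(mask, origin = c("global", "pot")) {
  origin <- match.arg(origin)
  storage.mode(mask) <- "integer"
  if (any(mask != 0L & mask != 1L)) stop("mask values must be 0/1")
  structure(list(mask = mask, origin = origin), class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask:%s> %d x %d, %d foreground px\n", x$origin,
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Fuse the clustering and Lab leaf masks
#'
#' Pixelwise union of the two routes, followed by removal of connected
#' components below a minimum area (default the pixel equivalent of 1 mm^2).
#' The union maximises recall; pot-level refinement later restores
#' precision.
#'
#' @param a,b `leaf_mask` objects of equal dimensions.
#' @param min_area_px minimum connected-component area in pixels.
#' @return The combined `leaf_mask`.
#' @export
combine_masks <- function(a, b, min_area_px = 0) {
  stopifnot(inherits(a, "leaf_mask"), inherits(b, "leaf_mask"))
  if (!identical(dim(a$mask), dim(b$mask)))
    stop("mask dimensions differ")
  u <- pmax(a$mask, b$mask)
  u <- remove_small_components(u, min_area_px)
  leaf_mask(u, a$origin)
}

#' Image-level leaf segmentation
#'
#' Convenience wrapper running both segmentation routes on a calibrated
#' image and fusing them: greenness k-means mask, Lab opponent mask, union,
#' small-object removal at 1 mm^2 equivalent.
#'
#' @param img a denoised [calibrated_image()].
#' @param k colour-group count (from [estimate_colour_groups()]).
#' @param cfg a [clustering_config()].
#' @param min_area_mm2 minimum object area in mm^2.
#' @return A global `leaf_mask`.
#' @export
segment_leaves <- function(img, k, cfg = clustering_config(),
                           min_area_mm2 = 1) {
  gv <- compute_greenness_img(img)
  mk <- kmeans_leaf_mask(gv, k, cfg)
  ml <- lab_leaf_mask(img)
  combine_masks(mk, ml,
                min_area_px = min_area_mm2 * img$scale$px_per_mm^2)
}
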