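#' Projected leaf area
#'
#' Foreground pixel count of the pot mask converted to mm^2 via the image
#' scale; 0 for an empty (e.g. harvested) pot.
#'
#' @param pot a `pot_mask`.
#' @param scale an `image_scale`.
#' @return Area in mm^2.
#' @export
projected_leaf_area <- function(pot, scale) {
  sum(pot$mask) / scale$px_per_mm^2
}

#' Leaf perimeter
#'
#' Total length of the contour enclosing each detected leaf component,
#' summed over components and converted to mm; 0 for an empty mask.
#'
#' @param pot a `pot_mask`.
#' @param scale an `image_scale`.
#' @return Perimeter in mm.
#' @export
leaf_perimeter <- function(pot, scale) {
  m <- pot$mask
  if (!any(m > 0L)) return(0)
  labels <- label_mask(m)
  contours <- EBImage::ocontour(labels)
  total <- 0
  for (ct in contours) {
    if (nrow(ct) < 2L) next
    nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
    total <- total + sum(sqrt(rowSums((nxt - ct)^2)))
  }
  total / scale$px_per_mm
}

#' Daily relative growth rate
#'
#' Growth statistic between two consecutive images of the same pot:
#' `(ln(area2) - ln(area1)) / ln(area1) / dt_days`. An earlier area of
#' exactly 1 mm^2 makes the denominator zero; the rate is then undefined and
#' reported as `NA`. Note this normalised form (division by `ln(area1)`)
#' differs from the classical RGR `(ln A2 - ln A1)/dt`.
#'
#' @param area1_mm2 projected leaf area of the earlier image (mm^2, > 0).
#' @param area2_mm2 projected leaf area of the later image (mm^2, > 0).
#' @param dt_days duration between the two images in days (> 0).
#' @return Per-day rate, or `NA` when `area1_mm2 == 1`.
#' @export
daily_rgr <- function(area1_mm2, area2_mm2, dt_days) {
  if (dt_days <= 0) stop("'dt_days' must be positive")
  if (area1_mm2 <= 0 || area2_mm2 <= 0)
    stop("areas must be positive")
  la1 <- log(area1_mm2)
  if (abs(la1) < 1e-12) return(NA_real_)
  (log(area2_mm2) - la1) / la1 / dt_days
}

#' Convex hull metrics of a pot mask
#'
#' The convex hull is taken over the corners of every foreground pixel (so
#' it contains the full pixel squares and its area is never below the
#' projected area). Hull length is the maximal point-to-point extent (major
#' axis); hull width the minimal extent over all support directions (minor
#' axis); both rotation-invariant and in mm.
#'
#' @param pot a `pot_mask`.
#' @param scale an `image_scale`.
#' @return List with `hull_area_mm2`, `hull_length_mm`, `hull_width_mm`,
#'   and `hull_mask` (binary matrix of the rasterised hull). All zeros and
#'   an empty mask for an empty pot.
#' @export
convex_hull_metrics <- function(pot, scale) {
  m <- pot$mask
  empty <- list(hull_area_mm2 = 0, hull_length_mm = 0, hull_width_mm = 0,
                hull_mask = matrix(0L, nrow(m), ncol(m)))
  idx <- which(m > 0L)
  if (length(idx) == 0L) return(empty)
  rows <- (idx - 1L) %% nrow(m) + 1L
  cols <- (idx - 1L) %/% nrow(m) + 1L
  hull <- pixel_hull(cbind(cols, rows))    # (x, y) vertices in order
  ppm <- scale$px_per_mm
  area <- polygon_area(hull) / ppm^2
  d2 <- as.matrix(stats::dist(hull))
  len <- max(d2) / ppm
  wid <- hull_min_width(hull) / ppm
  list(hull_area_mm2 = area, hull_length_mm = len,
       hull_width_mm = min(wid, len),
       hull_mask = rasterise_polygon(hull, nrow(m), ncol(m)))
}

# Minimal width of a convex polygon: smallest extent of the vertex set
# perpendicular to each edge direction (rotating calipers).
hull_min_width <- function(hull) {
  n <- nrow(hull)
  if (n < 3L) return(0)
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    L <- sqrt(sum(e^2))
    if (L < 1e-9) next
    nrm <- c(-e[2], e[1]) / L
    proj <- hull %*% nrm
    wmin <- min(wmin, max(proj) - min(proj))
  }
  if (is.finite(wmin)) wmin else 0
}

# Even-odd scanline fill of a polygon onto an H x W grid of pixel centres.
rasterise_polygon <- function(poly, H, W) {
  out <- matrix(0L, H, W)
  n <- nrow(poly)
  if (n < 3L) return(out)
  px <- poly[, 1]; py <- poly[, 2]
  for (y in seq_len(H)) {
    xin <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- py[i]; y2 <- py[j]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        xin <- c(xin, px[i] + (y - y1) / (y2 - y1) * (px[j] - px[i]))
      }
    }
    if (length(xin) >= 2L) {
      xin <- sort(xin)
      for (s in seq(1, length(xin) - 1, by = 2)) {
        a <- ceiling(xin[s]); b <- floor(xin[s + 1])
        if (b >= a) out[y, max(1, a):min(W, b)] <- 1L
      }
    }
  }
  out
}

#' Stockiness
#'
#' `100 * (4 pi Area) / (2 pi R)^2` with `R` half the convex-hull major
#' axis: 100% for a perfect circle, lower for elongated or serrated
#' rosettes. Capped at 100; 0 by convention for an empty pot.
#'
#' @param area_mm2 projected leaf area (mm^2).
#' @param hull_length_mm convex-hull major axis (mm).
#' @return Stockiness in percent.
#' @export
stockiness <- function(area_mm2, hull_length_mm) {
  if (hull_length_mm <= 0) return(0)
  R <- hull_length_mm / 2
  min(100, 100 * (4 * pi * area_mm2) / (2 * pi * R)^2)
}

#' Compactness
#'
#' Ratio of projected leaf area to convex-hull area, in percent
#' (100% for a convex rosette); 0 for an empty pot.
#'
#' @param area_mm2 projected leaf area (mm^2).
#' @param hull_area_mm2 convex-hull area (mm^2).
#' @return Compactness in percent.
#' @export
compactness <- function(area_mm2, hull_area_mm2) {
  if (hull_area_mm2 <= 0) return(0)
  min(100, 100 * area_mm2 / hull_area_mm2)
}

#' Mean greenness within the convex hull
#'
#' Mean of the clipped vegetative greenness `G_V` over the hull region
#' (0--255); 0 for an empty hull. Averaging over the hull rather than only
#' leaf pixels follows the trait's definition; soil inside the hull lowers
#' the reading.
#'
#' @param img the [calibrated_image()] sub-image the hull refers to (pot
#'   bounding box), or any image of matching size.
#' @param hull_mask binary matrix from [convex_hull_metrics()].
#' @return Mean greenness in `[0, 255]`.
#' @export
greenness_mean <- function(img, hull_mask) {
  if (!any(hull_mask > 0L)) return(0)
  gv <- compute_greenness_img(list(pixels = img$pixels))$values
  if (!identical(dim(gv), dim(hull_mask)))
    stop("hull mask does not match the image")
  mean(gv[hull_mask > 0L])
}

#' Measure all shape traits of one pot
#'
#' @param pot a refined `pot_mask`.
#' @param img the denoised [calibrated_image()] (full ROI; the pot bounding
#'   box is cropped internally).
#' @param scale an `image_scale`.
#' @return Named list of trait values (area, perimeter, hull metrics,
#'   stockiness, compactness, greenness).
#' @export
measure_pot_traits <- function(pot, img, scale) {
  bb <- pot$region$bbox
  sub <- list(pixels = img$pixels[bb[1]:bb[3], bb[2]:bb[4], , drop = FALSE])
  area <- projected_leaf_area(pot, scale)
  per <- leaf_perimeter(pot, scale)
  hull <- convex_hull_metrics(pot, scale)
  list(
    area_mm2 = area,
    perimeter_mm = per,
    hull_area_mm2 = hull$hull_area_mm2,
    hull_length_mm = hull$hull_length_mm,
    hull_width_mm = hull$hull_width_mm,
    stockiness_pct = stockiness(area, hull$hull_length_mm),
    compactness_pct = compactness(area, hull$hull_area_mm2),
    greenness = greenness_mean(sub, hull$hull_mask)
  )
}
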