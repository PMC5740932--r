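#' Rescale an image to a fixed working height
#'
#' All images of a series are brought to a common height (default 1024 px)
#' before analysis, so that every downstream pixel measurement shares one
#' coordinate frame and memory use stays bounded for large camera images.
#' The width follows the aspect ratio; the input object is not modified.
#'
#' @param img a [tray_image()].
#' @param target_height working height in pixels.
#' @return A [tray_image()] of height `target_height`.
#' @export
rescale_to_height <- function(img, target_height = 1024L) {
  stopifnot(inherits(img, "tray_image"))
  if (target_height < 1) stop("'target_height' must be positive")
  h <- img_height(img); w <- img_width(img)
  if (h == target_height) return(img)
  new_w <- max(1L, as.integer(round(w * target_height / h)))
  eb <- array_to_ebimage(img$pixels)
  out <- EBImage::resize(eb, w = new_w, h = target_height)
  px <- pmax(pmin(aperm(EBImage::imageData(out), c(2, 1, 3)) * 255, 255), 0)
  tray_image(px, img$source_name, img$capture_time)
}

#' Red-marker pixel rule
#'
#' Multi-threshold rule classifying a pixel as belonging to a red circular
#' reference marker: red channel above 125, blue channel below 225, and
#' red exceeding green by more than 50 (all on the 0--255 scale). Vectorised
#' over its arguments.
#'
#' @param r,g,b channel values in `[0, 255]`.
#' @return integer vector of 0/1.
#' @export
marker_threshold <- function(r, g, b) {
  as.integer(r > 125 & b < 225 & (r - g) > 50)
}

# Binary marker mask of a whole image.
marker_mask <- function(img) {
  px <- img$pixels
  m <- matrix(marker_threshold(px[, , 1], px[, , 2], px[, , 3]),
              nrow = dim(px)[1])
  m
}

#' Detect the four red circular reference markers
#'
#' Thresholds the image with [marker_threshold()], labels connected
#' components and filters candidates by shape: solidity >= 0.9, eccentricity
#' <= 0.6 and area within \[0.25x, 4x\] of the median candidate area. If more
#' than four candidates survive, the four nearest the image corners are
#' retained. Marker radii are equivalent-circle radii (`sqrt(area/pi)`).
#'
#' @param img the rescaled working image ([tray_image()]).
#' @param min_area_px discard specks below this area before shape filtering.
#' @return A `marker_set`: list with `markers` (data.frame `cx`, `cy`,
#'   `radius` in px) and `mean_radius_px`.
#' @export
detect_reference_markers <- function(img, min_area_px = 20) {
  stopifnot(inherits(img, "tray_image"))
  m <- marker_mask(img)
  # 3x3 opening detaches stray red-passing speckles from the discs
  m <- EBImage::imageData(EBImage::opening(EBImage::Image(m),
                                           EBImage::makeBrush(3, "box")))
  storage.mode(m) <- "integer"
  labels <- label_mask(m)
  st <- component_stats(labels, min_area = min_area_px)
  if (nrow(st) > 0) {
    med <- stats::median(st$area)
    st <- st[st$solidity >= 0.9 & st$eccentricity <= 0.6 &
               st$area >= 0.25 * med & st$area <= 4 * med, , drop = FALSE]
  }
  if (nrow(st) < 4L)
    stop("marker detection failed: found ", nrow(st),
         " circular marker candidate(s), need 4")
  if (nrow(st) > 4L) {
    h <- img_height(img); w <- img_width(img)
    corners <- rbind(c(1, 1), c(1, w), c(h, 1), c(h, w))
    pick <- integer(4)
    avail <- seq_len(nrow(st))
    for (i in 1:4) {
      d <- sqrt((st$cy[avail] - corners[i, 1])^2 +
                  (st$cx[avail] - corners[i, 2])^2)
      pick[i] <- avail[which.min(d)]
      avail <- setdiff(avail, pick[i])
    }
    st <- st[sort(pick), , drop = FALSE]
  }
  markers <- data.frame(cx = st$cx, cy = st$cy, radius = st$radius)
  structure(list(markers = markers,
                 mean_radius_px = mean(markers$radius)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> 4 markers, mean radius %.2f px\n",
              x$mean_radius_px))
  invisible(x)
}

#' Derive the pixel-to-mm scale from the markers
#'
#' The mean marker radius in pixels divided by the known physical radius
#' (4 mm for the standard stickers, 5 mm for the wheat setting) gives the
#' image scale in pixels per millimetre.
#'
#' @param markers a `marker_set` from [detect_reference_markers()].
#' @param marker_radius_mm physical marker radius in mm.
#' @return An `image_scale` object (fields `px_per_mm`, `marker_radius_mm`).
#' @export
compute_scale <- function(markers, marker_radius_mm = 4) {
  stopifnot(inherits(markers, "marker_set"))
  if (marker_radius_mm <= 0) stop("'marker_radius_mm' must be positive")
  if (markers$mean_radius_px <= 0) stop("degenerate scale: zero marker radius")
  image_scale(markers$mean_radius_px / marker_radius_mm, marker_radius_mm)
}

#' @rdname compute_scale
#' @param px_per_mm pixels per millimetre.
#' @export
image_scale <- function(px_per_mm, marker_radius_mm = 4) {
  if (px_per_mm <= 0 || marker_radius_mm <= 0)
    stop("scale parameters must be positive")
  structure(list(px_per_mm = px_per_mm, marker_radius_mm = marker_radius_mm),
            class = "image_scale")
}

# Order 4 marker centres (cx, cy) as top-left, top-right, bottom-right,
# bottom-left: sort by angle about the common centroid (image y grows
# downwards, so increasing angle runs clockwise on screen), then rotate the
# cycle so the corner nearest the top-left (minimal x + y) comes first.
order_corners <- function(pts) {
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  ang <- atan2(pts[, 2] - cy, pts[, 1] - cx)
  o <- order(ang)
  pts <- pts[o, , drop = FALSE]
  first <- which.min(pts[, 1] + pts[, 2])
  pts[((seq_len(4) + first - 2L) %% 4L) + 1L, , drop = FALSE]
}

# 3x3 homography mapping (x, y) in `from` to the corresponding point in
# `to`; both are 4x2 matrices of corresponding corners.
solve_homography <- function(from, to) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- from[i, 1]; y <- from[i, 2]
    u <- to[i, 1]; v <- to[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * u, -y * u)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -x * v, -y * v)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    stop("degenerate marker geometry: corners are collinear or coincident"))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Extract the marker-bounded tray region
#'
#' The quadrilateral through the four marker centres is mapped to an
#' axis-aligned rectangle by a perspective transform (inverse mapping with
#' bilinear resampling). The output width is the mean of the two horizontal
#' marker-to-marker distances and the height the mean of the two vertical
#' distances, which minimises anisotropic distortion.
#'
#' @param img the rescaled working image.
#' @param markers a `marker_set`.
#' @param scale the `image_scale` for the working image.
#' @return A [calibrated_image()] containing the enclosed region.
#' @export
extract_tray_roi <- function(img, markers, scale) {
  stopifnot(inherits(img, "tray_image"), inherits(markers, "marker_set"),
            inherits(scale, "image_scale"))
  if (nrow(markers$markers) != 4L) stop("exactly 4 markers are required")
  pts <- order_corners(as.matrix(markers$markers[, c("cx", "cy")]))
  edge <- function(a, b) sqrt(sum((pts[a, ] - pts[b, ])^2))
  out_w <- round(mean(c(edge(1, 2), edge(4, 3))))
  out_h <- round(mean(c(edge(1, 4), edge(2, 3))))
  if (out_w < 2 || out_h < 2)
    stop("degenerate marker geometry: ROI collapses")
  dst <- rbind(c(1, 1), c(out_w, 1), c(out_w, out_h), c(1, out_h))
  H <- solve_homography(dst, pts)
  # inverse mapping: for each output pixel find its source location
  gx <- rep(seq_len(out_w), each = out_h)
  gy <- rep(seq_len(out_h), times = out_w)
  den <- H[3, 1] * gx + H[3, 2] * gy + H[3, 3]
  sx <- (H[1, 1] * gx + H[1, 2] * gy + H[1, 3]) / den
  sy <- (H[2, 1] * gx + H[2, 2] * gy + H[2, 3]) / den
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  sx <- pmin(pmax(sx, 1), w); sy <- pmin(pmax(sy, 1), h)
  x0 <- pmin(floor(sx), w - 1L); y0 <- pmin(floor(sy), h - 1L)
  fx <- sx - x0; fy <- sy - y0
  out <- array(0, dim = c(out_h, out_w, 3))
  for (ch in 1:3) {
    pl <- px[, , ch]
    i00 <- (x0 - 1) * h + y0
    v <- pl[i00] * (1 - fx) * (1 - fy) + pl[i00 + h] * fx * (1 - fy) +
      pl[i00 + 1] * (1 - fx) * fy + pl[i00 + h + 1] * fx * fy
    out[, , ch] <- matrix(v, out_h, out_w)
  }
  calibrated_image(out, scale, img$source_name, img$capture_time)
}

#' Denoise a calibrated image
#'
#' Edge-preserving median smoothing (radius 2 px) applied per channel to
#' suppress soil speckle and sensor noise before leaf segmentation. The
#' dimensions and scale are unchanged.
#'
#' @param img a [calibrated_image()].
#' @param radius median filter radius in pixels.
#' @return The smoothed [calibrated_image()].
#' @export
denoise <- function(img, radius = 2L) {
  stopifnot(inherits(img, "calibrated_image"))
  eb <- array_to_ebimage(img$pixels)
  sm <- EBImage::medianFilter(eb, radius)
  px <- pmax(pmin(aperm(EBImage::imageData(sm), c(2, 1, 3)) * 255, 255), 0)
  calibrated_image(px, img$scale, img$source_name, img$capture_time)
}
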