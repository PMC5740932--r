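# Shift a matrix by (dy, dx), filling vacated cells with 0.
shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  ys <- max(1, 1 - dy):min(H, H - dy)
  xs <- max(1, 1 - dx):min(W, W - dx)
  out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

# 8-neighbourhood stack in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W,
# NW), with image y growing downwards.
neighbour_stack <- function(m) {
  list(
    p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
    p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
    p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
    p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1)
  )
}

#' Skeletonise a pot mask
#'
#' Zhang-Suen thinning to a 1-px-wide skeleton. The skeleton is a subset of
#' the input foreground; an empty mask yields an empty skeleton.
#'
#' @param pot a `pot_mask`, `leaf_mask`, or plain binary matrix.
#' @return Binary matrix of the skeleton.
#' @export
skeletonize_mask <- function(pot) {
  m0 <- if (is.matrix(pot)) pot else pot$mask
  storage.mode(m0) <- "integer"
  if (!any(m0 > 0L)) return(m0)
  # thin only within the foreground bounding box (padded 1 px): the
  # result is identical and large mostly-empty pot matrices stay cheap
  idx <- which(m0 > 0L)
  ys <- range((idx - 1L) %% nrow(m0) + 1L)
  xs <- range((idx - 1L) %/% nrow(m0) + 1L)
  ys <- c(max(1L, ys[1] - 1L), min(nrow(m0), ys[2] + 1L))
  xs <- c(max(1L, xs[1] - 1L), min(ncol(m0), xs[2] + 1L))
  m <- m0[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- neighbour_stack(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
                   nb$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8)
        A <- A + as.integer(seqn[[i]] == 0L & seqn[[i + 1L]] == 1L)
      if (pass == 1) {
        cond <- nb$p2 * nb$p4 * nb$p6 == 0L & nb$p4 * nb$p6 * nb$p8 == 0L
      } else {
        cond <- nb$p2 * nb$p4 * nb$p8 == 0L & nb$p2 * nb$p6 * nb$p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- m0 * 0L
  out[ys[1]:ys[2], xs[1]:xs[2]] <- m
  out
}

#' Find skeleton end points (leaf tips)
#'
#' Hit-or-miss matching of the four end-point kernels: a foreground pixel
#' whose far side and both laterals are background, in each of the four
#' orientations (up, down, left, right). Diagonal line ends match too, since
#' the diagonal continuation pixel is a don't-care in every kernel.
#'
#' @param skeleton binary skeleton matrix.
#' @return Integer matrix with columns `x` (col) and `y` (row), one row per
#'   unique end point.
#' @export
find_end_points <- function(skeleton) {
  m <- skeleton
  storage.mode(m) <- "integer"
  if (!any(m > 0L))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  nb <- neighbour_stack(m)
  N <- nb$p2; NE <- nb$p3; E <- nb$p4; SE <- nb$p5
  S <- nb$p6; SW <- nb$p7; W <- nb$p8; NW <- nb$p9
  hit <- m == 1L & (
    (N == 0L & NW == 0L & NE == 0L & W == 0L & E == 0L) |
    (S == 0L & SW == 0L & SE == 0L & W == 0L & E == 0L) |
    (W == 0L & NW == 0L & SW == 0L & N == 0L & S == 0L) |
    (E == 0L & NE == 0L & SE == 0L & N == 0L & S == 0L))
  idx <- which(hit)
  cbind(x = (idx - 1L) %/% nrow(m) + 1L,
        y = (idx - 1L) %% nrow(m) + 1L)
}

# Remove branch tips iteratively: each iteration deletes every pixel with
# at most one 8-neighbour (a classical spur end), so spurs shorter than
# n_iter pixels disappear entirely while long branches are only shortened
# and connectivity is never broken. Used to de-noise skeletons of
# rasterised leaf shapes before tip counting.
prune_skeleton <- function(skeleton, n_iter) {
  m0 <- skeleton
  if (!any(m0 > 0L)) return(m0)
  idx <- which(m0 > 0L)
  ys <- range((idx - 1L) %% nrow(m0) + 1L)
  xs <- range((idx - 1L) %/% nrow(m0) + 1L)
  ys <- c(max(1L, ys[1] - 1L), min(nrow(m0), ys[2] + 1L))
  xs <- c(max(1L, xs[1] - 1L), min(ncol(m0), xs[2] + 1L))
  m <- m0[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE]
  for (i in seq_len(n_iter)) {
    nb <- neighbour_stack(m)
    deg <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
    tip <- m == 1L & deg <= 1L
    if (!any(tip)) break
    m[tip] <- 0L
  }
  out <- m0 * 0L
  out[ys[1]:ys[2], xs[1]:xs[2]] <- m
  out
}

#' Build the skeleton graph of a pot
#'
#' The mask centroid and the skeleton end points are the vertices; each end
#' point contributes one edge weighted by (a) the geodesic length along the
#' skeleton from the centroid-nearest skeleton pixel to the end point, in
#' mm, and (b) a leaf-area weight: the area of the mask component containing
#' the end point divided by that component's end-point count, in mm^2.
#'
#' @param pot a `pot_mask`.
#' @param scale an `image_scale`.
#' @param prune_mm spur-pruning length in mm applied before end-point
#'   detection.
#' @return A `skeleton_graph`: list with `centroid` (x, y), `endpoints`,
#'   `edges` (data.frame `length_mm`, `leaf_area_mm2`) and `skeleton`.
#' @export
skeleton_graph <- function(pot, scale, prune_mm = 2) {
  m <- pot$mask
  ppm <- scale$px_per_mm
  empty <- structure(list(centroid = c(x = NA_real_, y = NA_real_),
                          endpoints = matrix(integer(0), ncol = 2),
                          edges = data.frame(length_mm = numeric(0),
                                             leaf_area_mm2 = numeric(0)),
                          skeleton = m * 0L),
                     class = "skeleton_graph")
  if (!any(m > 0L)) return(empty)
  skel <- skeletonize_mask(m)
  skel <- prune_skeleton(skel, max(3L, as.integer(round(prune_mm * ppm))))
  ep <- find_end_points(skel)
  idx <- which(m > 0L)
  cy <- mean((idx - 1L) %% nrow(m) + 1L)
  cx <- mean((idx - 1L) %/% nrow(m) + 1L)
  if (nrow(ep) == 0L) {
    out <- empty
    out$centroid <- c(x = cx, y = cy)
    out$skeleton <- skel
    return(out)
  }
  sk_idx <- which(skel > 0L)
  sy <- (sk_idx - 1L) %% nrow(skel) + 1L
  sx <- (sk_idx - 1L) %/% nrow(skel) + 1L
  g <- skeleton_pixel_graph(sk_idx, nrow(skel), ncol(skel), skel)
  root <- which.min((sy - cy)^2 + (sx - cx)^2)
  node_of <- match((ep[, "x"] - 1L) * nrow(skel) + ep[, "y"], sk_idx)
  dists <- igraph::distances(g, v = root, to = node_of)[1, ]
  labels <- label_mask(m)
  comp_of <- labels[cbind(ep[, "y"], ep[, "x"])]
  comp_area <- tabulate(labels[labels > 0L], nbins = max(labels))
  ep_per_comp <- tabulate(comp_of, nbins = max(labels))
  edges <- data.frame(
    length_mm = as.numeric(dists) / ppm,
    leaf_area_mm2 = comp_area[comp_of] / pmax(1L, ep_per_comp[comp_of]) /
      ppm^2
  )
  structure(list(centroid = c(x = cx, y = cy), endpoints = ep,
                 edges = edges, skeleton = skel),
            class = "skeleton_graph")
}

# Weighted 8-connected pixel adjacency graph over skeleton pixels.
skeleton_pixel_graph <- function(sk_idx, H, W, skel) {
  pos <- match(seq_len(H * W), sk_idx)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
               c(-1L, 1L, sqrt(2)))
  y <- (sk_idx - 1L) %% H + 1L
  x <- (sk_idx - 1L) %/% H + 1L
  for (o in offs) {
    ny <- y + o[1]; nx <- x + o[2]
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
    tgt <- rep(NA_integer_, length(ny))
    tgt[ok] <- pos[(nx[ok] - 1L) * H + ny[ok]]
    sel <- !is.na(tgt)
    from <- c(from, which(sel)); to <- c(to, tgt[sel])
    wt <- c(wt, rep(o[3], sum(sel)))
  }
  g <- igraph::make_empty_graph(n = length(sk_idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  g
}

#' Count long or large leaves
#'
#' Edges of the skeleton graph whose geodesic length exceeds
#' `length_thresh_mm` (default 15 mm) or whose leaf-area weight exceeds
#' `area_thresh_mm2` (default 100 mm^2) are counted as long/large leaves.
#'
#' @param graph a [skeleton_graph()].
#' @param length_thresh_mm length threshold in mm.
#' @param area_thresh_mm2 area threshold in mm^2.
#' @return Integer count.
#' @export
classify_large_leaves <- function(graph, length_thresh_mm = 15,
                                  area_thresh_mm2 = 100) {
  e <- graph$edges
  sum(e$length_mm > length_thresh_mm | e$leaf_area_mm2 > area_thresh_mm2)
}

#' Centroid-to-contour distance series
#'
#' For each integer degree 0--359, the squared Euclidean distance (px^2)
#' from the mask centroid to the farthest outline pixel whose polar angle
#' falls in that degree bin; empty bins are interpolated circularly. The
#' series is then smoothed with a circular Gaussian kernel.
#'
#' @param pot a non-empty `pot_mask` (or binary matrix).
#' @param sigma Gaussian smoothing width in degrees.
#' @return A `distance_series`: list with `values`, `smoothed` (length-360
#'   numeric vectors) and `sigma`.
#' @export
outline_distance_series <- function(pot, sigma = 3) {
  m <- if (is.matrix(pot)) pot else pot$mask
  if (!any(m > 0L)) stop("cannot sweep an empty mask")
  idx <- which(m > 0L)
  y <- (idx - 1L) %% nrow(m) + 1L
  x <- (idx - 1L) %/% nrow(m) + 1L
  cy <- mean(y); cx <- mean(x)
  # outline = foreground pixels with a 4-neighbour outside the foreground
  nb4 <- shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1)
  border <- m == 1L & nb4 < 4L
  bidx <- which(border)
  by <- (bidx - 1L) %% nrow(m) + 1L
  bx <- (bidx - 1L) %/% nrow(m) + 1L
  ang <- (atan2(by - cy, bx - cx) * 180 / pi) %% 360
  d2 <- (by - cy)^2 + (bx - cx)^2
  bin <- floor(ang) + 1L
  vals <- rep(NA_real_, 360)
  agg <- tapply(d2, bin, max)
  vals[as.integer(names(agg))] <- agg
  vals <- interpolate_circular(vals)
  structure(list(values = vals,
                 smoothed = gaussian_smooth_circular(vals, sigma),
                 sigma = sigma),
            class = "distance_series")
}

# Linear interpolation across NA runs on a circular series.
interpolate_circular <- function(v) {
  n <- length(v)
  filled <- which(!is.na(v))
  if (length(filled) == 0L) return(rep(0, n))
  if (length(filled) == n) return(v)
  # unroll: extend with the first filled point shifted by n on both sides
  xs <- c(filled[length(filled)] - n, filled, filled[1] + n)
  ys <- c(v[filled[length(filled)]], v[filled], v[filled[1]])
  miss <- which(is.na(v))
  v[miss] <- stats::approx(xs, ys, xout = miss)$y
  v
}

gaussian_smooth_circular <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  kk <- stats::dnorm(-r:r, sd = sigma)
  kk <- kk / sum(kk)
  n <- length(v)
  ext <- c(v[(n - r + 1L):n], v, v[1:r])
  stats::filter(ext, kk, sides = 2)[(r + 1L):(r + n)]
}

#' Count peaks of a distance series
#'
#' Local maxima of the smoothed circular series (0 deg adjacent to 359 deg)
#' whose prominence reaches `prominence_frac` of the series range. A nearly
#' flat series (range below `flat_frac` of the mean) reads as a single
#' disc-like leaf object, returning 1.
#'
#' @param series a `distance_series`.
#' @param prominence_frac prominence floor as a fraction of (max - min).
#' @param flat_frac flatness guard as a fraction of the mean.
#' @return Integer peak count.
#' @export
detect_leaf_tip_peaks <- function(series, prominence_frac = 0.05,
                                  flat_frac = 0.02) {
  v <- as.numeric(series$smoothed)
  n <- length(v)
  rng <- max(v) - min(v)
  if (rng < flat_frac * mean(v)) return(1L)
  nxt <- c(v[-1], v[1]); prv <- c(v[n], v[-n])
  d <- sign(v - prv)
  # propagate through plateaus
  for (i in seq_len(n)) if (d[i] == 0) d[i] <- d[if (i == 1) n else i - 1]
  if (all(d == 0)) return(1L)
  dn <- c(d[-1], d[1])
  peaks <- which(d > 0 & dn < 0)
  floor_p <- prominence_frac * rng
  count <- 0L
  for (p in peaks) {
    if (circular_prominence(v, p) >= floor_p) count <- count + 1L
  }
  count
}

# Prominence of peak p on a circular series: drop to the higher of the two
# minima encountered before reaching a strictly higher value on each side.
circular_prominence <- function(v, p) {
  n <- length(v)
  walk <- function(step) {
    lo <- v[p]; i <- p
    for (s in seq_len(n - 1L)) {
      i <- ((i - 1L + step) %% n) + 1L
      if (v[i] > v[p]) return(lo)
      lo <- min(lo, v[i])
    }
    lo
  }
  minL <- walk(-1L); minR <- walk(1L)
  v[p] - max(minL, minR)
}

#' Combine the two leaf-count estimates
#'
#' The skeleton route misses small central leaves and the sweeping route
#' merges overlapping tips, so each under-counts in known cases; the
#' combined count is the maximum of the two.
#'
#' @param skeleton_tips end-point count from the skeleton route.
#' @param sweep_peaks peak count from the distance-series route.
#' @return Integer combined count.
#' @export
combined_leaf_count <- function(skeleton_tips, sweep_peaks) {
  stopifnot(skeleton_tips >= 0, sweep_peaks >= 0)
  max(as.integer(skeleton_tips), as.integer(sweep_peaks))
}

#' Leaf counts of one pot
#'
#' Runs both counting routes on a refined pot mask and combines them.
#' Unreliable for wheat (complex canopy architecture); the pipeline emits
#' empty leaf-count fields for wheat series.
#'
#' @param pot a `pot_mask`.
#' @param scale an `image_scale`.
#' @param length_thresh_mm,area_thresh_mm2 large-leaf thresholds.
#' @return A `leaf_count_result`: list with `skeleton_tips`, `sweep_peaks`,
#'   `combined`, `large_leaves`.
#' @export
count_leaves <- function(pot, scale, length_thresh_mm = 15,
                         area_thresh_mm2 = 100) {
  if (!any(pot$mask > 0L))
    return(structure(list(skeleton_tips = 0L, sweep_peaks = 0L,
                          combined = 0L, large_leaves = 0L),
                     class = "leaf_count_result"))
  gr <- skeleton_graph(pot, scale)
  tips <- nrow(gr$endpoints)
  series <- outline_distance_series(pot)
  peaks <- detect_leaf_tip_peaks(series)
  structure(list(
    skeleton_tips = as.integer(tips),
    sweep_peaks = as.integer(peaks),
    combined = combined_leaf_count(tips, peaks),
    large_leaves = classify_large_leaves(gr, length_thresh_mm,
                                         area_thresh_mm2)
  ), class = "leaf_count_result")
}
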