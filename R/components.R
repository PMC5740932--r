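# Connected-component helpers shared by the calibration, segmentation and
# pot-refinement steps. Labelling is done by EBImage::bwlabel (8-connectivity);
# shape statistics are computed from the pixel coordinates directly.

label_mask <- function(mask) {
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)      # 4-connected labels
  n <- max(lab)
  if (n < 2L) return(lab)
  # merge labels that touch diagonally to obtain 8-connectivity
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  ys <- seq_len(H - 1L); xs <- seq_len(W - 1L)
  for (diag in 1:2) {
    if (diag == 1L) {  # (y, x+1) vs (y+1, x)
      a <- lab[ys, xs + 1L, drop = FALSE]; b <- lab[ys + 1L, xs, drop = FALSE]
    } else {           # (y, x) vs (y+1, x+1)
      a <- lab[ys, xs, drop = FALSE]; b <- lab[ys + 1L, xs + 1L, drop = FALSE]
    }
    touch <- which(a > 0L & b > 0L & a != b)
    for (t in touch) {
      ra <- find(a[t]); rb <- find(b[t])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Per-component statistics: area (px), centroid (row, col), equivalent-circle
# radius, and (with shape = TRUE) eccentricity of the second-moment ellipse
# and solidity (area / convex hull area over pixel corners). Components
# below min_area are dropped before any expensive per-component work.
component_stats <- function(labels, min_area = 1, shape = TRUE) {
  empty <- data.frame(label = integer(), area = numeric(), cy = numeric(),
                      cx = numeric(), radius = numeric(),
                      eccentricity = numeric(), solidity = numeric())
  n <- max(labels)
  if (n == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  area_all <- tabulate(lab, nbins = n)
  keep <- which(area_all >= min_area)
  if (length(keep) == 0L) return(empty)
  sel <- lab %in% keep
  y <- (idx[sel] - 1L) %% nrow(labels) + 1L
  x <- (idx[sel] - 1L) %/% nrow(labels) + 1L
  f <- factor(lab[sel], levels = keep)
  a <- area_all[keep]
  cy <- rowsum(y, f)[, 1] / a
  cx <- rowsum(x, f)[, 1] / a
  st <- data.frame(label = keep, area = a, cy = cy, cx = cx,
                   radius = sqrt(a / pi),
                   eccentricity = NA_real_, solidity = NA_real_)
  if (shape) {
    muyy <- rowsum(y^2, f)[, 1] / a - cy^2 + 1 / 12
    muxx <- rowsum(x^2, f)[, 1] / a - cx^2 + 1 / 12
    muxy <- rowsum(as.numeric(x) * y, f)[, 1] / a - cx * cy
    common <- sqrt((muxx - muyy)^2 + 4 * muxy^2)
    l1 <- (muxx + muyy + common) / 2
    l2 <- (muxx + muyy - common) / 2
    st$eccentricity <- ifelse(l1 <= 0, 0, sqrt(pmax(0, 1 - l2 / l1)))
    st$solidity <- vapply(seq_along(keep), function(i) {
      pts <- cbind(x[f == levels(f)[i]], y[f == levels(f)[i]])
      ha <- polygon_area(pixel_hull(pts))
      if (ha > 0) min(1, a[i] / ha) else 1
    }, numeric(1))
  }
  st
}

# Mean of `values` over each kept component label.
component_means <- function(labels, values, keep) {
  sel <- labels > 0L & labels %in% keep
  f <- factor(labels[sel], levels = keep)
  rowsum(as.numeric(values[sel]), f)[, 1] /
    tabulate(f, nbins = length(keep))
}

# Convex hull over the 4 corners of every foreground pixel, so the hull
# polygon contains the full pixel squares (hull area >= pixel count).
pixel_hull <- function(xy) {
  if (nrow(xy) == 0L) return(xy)
  pts <- rbind(
    cbind(xy[, 1] - 0.5, xy[, 2] - 0.5),
    cbind(xy[, 1] + 0.5, xy[, 2] - 0.5),
    cbind(xy[, 1] - 0.5, xy[, 2] + 0.5),
    cbind(xy[, 1] + 0.5, xy[, 2] + 0.5)
  )
  pts[grDevices::chull(pts), , drop = FALSE]
}

# Shoelace formula; vertices in order, any orientation.
polygon_area <- function(p) {
  if (is.null(nrow(p)) || nrow(p) < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Drop connected components smaller than min_area pixels.
remove_small_components <- function(mask, min_area) {
  if (min_area <= 1 || !any(mask > 0)) return(mask)
  labels <- label_mask(mask)
  sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[labels %in% keep] <- 1L
  out
}

# Otsu threshold on a numeric matrix (256-bin histogram over the value range).
# Returns the threshold on the data scale; pixels strictly above it are
# "foreground". For a constant input the maximum value is returned, so that
# nothing lies above the threshold.
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps) return(hi)
  nb <- 256L
  h <- as.numeric(tabulate(pmin(nb, 1L + floor((v - lo) / (hi - lo) * nb)),
                           nbins = nb))
  w <- cumsum(h)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  m <- cumsum(h * mids)
  n <- w[nb]; mt <- m[nb]
  w1 <- w[-nb]; m1 <- m[-nb]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, nb - 1L)
  bc[valid] <- (mt * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * w2[valid])
  k <- which.max(bc)
  lo + k * (hi - lo) / nb
}
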