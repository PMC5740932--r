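#' Parameters for the synthetic tray generator
#'
#' Describes a rendered top-view tray photograph: soil-textured background,
#' four red circular fiducial markers at the tray corners, and per-pot
#' rosettes drawn as wavy rose-curve discs `r(theta) = L (0.6 + 0.4
#' cos(n theta))` whose `n` bumps emulate `n` well-separated leaves.
#' Defaults emulate the study conditions: a 2592 x 1944 camera frame, a
#' 4 x 6 pot tray, 4 mm markers, moderate soil speckle and optional algae.
#'
#' @param rows,cols pot lattice of the tray.
#' @param width,height image size in pixels.
#' @param marker_radius_px marker radius in pixels at native resolution.
#' @param marker_radius_mm physical marker radius (mm); with
#'   `marker_radius_px` this fixes the native scale.
#' @param margin_frac margin between image edge and marker centres, as a
#'   fraction of the smaller image dimension.
#' @param leaf_counts integer vector (length `rows*cols`, recycled) of
#'   petal counts per pot; `NULL` draws each from 4--9.
#' @param petal_radius_mm rosette radius `L` in mm (recycled per pot);
#'   `NULL` draws each from 14--20 mm.
#' @param harvested logical vector (recycled): `TRUE` leaves the pot empty.
#' @param algae add small bright-green algae speckles on the soil?
#' @param distractor_bar add a red 80 x 8 px bar (a non-circular red object
#'   that the marker filter must reject)?
#' @return A `synthetic_tray_params` list.
#' @export
synthetic_tray_params <- function(rows = 4L, cols = 6L,
                                  width = 2592L, height = 1944L,
                                  marker_radius_px = 22,
                                  marker_radius_mm = 4,
                                  margin_frac = 0.05,
                                  leaf_counts = NULL,
                                  petal_radius_mm = NULL,
                                  harvested = FALSE,
                                  algae = TRUE,
                                  distractor_bar = FALSE) {
  if (rows < 1L || cols < 1L) stop("'rows' and 'cols' must be >= 1")
  if (marker_radius_px <= 0) stop("'marker_radius_px' must be positive")
  if (!is.null(leaf_counts) && any(leaf_counts < 0))
    stop("leaf counts must be >= 0")
  structure(as.list(environment()), class = "synthetic_tray_params")
}

#' Render a synthetic tray image with exact ground truth
#'
#' Deterministic given `seed`. Returns the rendered image together with the
#' exact ground truth the renderer used: the full-frame leaf mask, per-pot
#' leaf pixel counts and areas in mm^2, per-pot leaf (petal) counts, marker
#' geometry and the native pixel-to-mm scale.
#'
#' @param params a [synthetic_tray_params()].
#' @param seed integer RNG seed.
#' @return List with `image` (a [tray_image()]) and `truth` (list:
#'   `leaf_mask`, `pot_leaf_px`, `pot_area_mm2`, `leaf_counts`, `harvested`,
#'   `markers` (centres + radius, px), `px_per_mm`, `pot_bbox` list, and the
#'   marker-rectangle `roi_bbox`).
#' @export
generate_synthetic_tray <- function(params = synthetic_tray_params(),
                                    seed = 1L) {
  stopifnot(inherits(params, "synthetic_tray_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  H <- as.integer(params$height); W <- as.integer(params$width)
  npot <- params$rows * params$cols
  ppm <- params$marker_radius_px / params$marker_radius_mm
  lc <- params$leaf_counts
  if (is.null(lc)) lc <- sample(4:9, npot, replace = TRUE)
  lc <- rep_len(as.integer(lc), npot)
  pr <- params$petal_radius_mm
  if (is.null(pr)) pr <- stats::runif(npot, 14, 20)
  pr <- rep_len(pr, npot)
  harvested <- rep_len(params$harvested, npot)

  # soil background: brown base + speckle noise + gritty dots
  base <- c(116, 86, 60)
  Rm <- base[1] + matrix(stats::runif(H * W, -18, 18), H, W)
  Gm <- base[2] + matrix(stats::runif(H * W, -18, 18), H, W)
  Bm <- base[3] + matrix(stats::runif(H * W, -18, 18), H, W)
  ngrit <- round(H * W / 3000)
  gidx <- (sample.int(W, ngrit, replace = TRUE) - 1L) * H +
    sample.int(H, ngrit, replace = TRUE)
  glum <- stats::runif(ngrit, -45, 45)
  Rm[gidx] <- Rm[gidx] + glum
  Gm[gidx] <- Gm[gidx] + glum
  Bm[gidx] <- Bm[gidx] + glum

  # markers at the four corners
  inset <- round(params$margin_frac * min(H, W)) +
    ceiling(params$marker_radius_px)
  mk <- rbind(c(inset, inset), c(inset, W - inset),
              c(H - inset, W - inset), c(H - inset, inset)) # (y,x) TL TR BR BL
  red <- c(228, 30, 32)
  for (i in 1:4) {
    idx <- disc_indices(mk[i, 1], mk[i, 2], params$marker_radius_px, H, W)
    nz <- stats::runif(length(idx), -6, 6)
    Rm[idx] <- red[1] + nz; Gm[idx] <- red[2] + nz; Bm[idx] <- red[3] + nz
  }
  if (params$distractor_bar) {
    by <- round(H / 2); bx <- round(W / 2)
    idx <- as.vector(outer((by - 3):(by + 4), ((bx - 39):(bx + 40) - 1L) * H,
                           `+`))
    Rm[idx] <- red[1]; Gm[idx] <- red[2]; Bm[idx] <- red[3]
  }

  # pot lattice inside the marker-centre rectangle
  y0 <- mk[1, 1]; y1 <- mk[3, 1]; x0 <- mk[1, 2]; x1 <- mk[3, 2]
  RH <- y1 - y0 + 1L; RW <- x1 - x0 + 1L
  ys <- y0 - 1L + round((0:params$rows) * RH / params$rows)
  xs <- x0 - 1L + round((0:params$cols) * RW / params$cols)
  leaf_mask <- matrix(FALSE, H, W)
  pot_bbox <- vector("list", npot)
  green <- c(46, 138, 52)
  for (r in seq_len(params$rows)) for (c in seq_len(params$cols)) {
    i <- (r - 1L) * params$cols + c
    bb <- c(ys[r] + 1L, xs[c] + 1L, ys[r + 1L], xs[c + 1L])
    pot_bbox[[i]] <- bb
    if (harvested[i] || lc[i] == 0L) next
    pot_h <- bb[3] - bb[1] + 1L; pot_w <- bb[4] - bb[2] + 1L
    L <- min(pr[i] * ppm, 0.42 * min(pot_h, pot_w))
    cy <- (bb[1] + bb[3]) / 2 + stats::runif(1, -0.06, 0.06) * pot_h
    cx <- (bb[2] + bb[4]) / 2 + stats::runif(1, -0.06, 0.06) * pot_w
    phase <- stats::runif(1, 0, 2 * pi)
    ro <- rosette_indices(cy, cx, L, lc[i], phase, H, W)
    shade <- 1 - 0.25 * ro$dist / L        # brighter centre, darker rim
    nz <- stats::runif(length(ro$idx), -8, 8)
    Rm[ro$idx] <- green[1] * shade + nz
    Gm[ro$idx] <- green[2] * shade + nz
    Bm[ro$idx] <- green[3] * shade + nz
    leaf_mask[ro$idx] <- TRUE
  }

  if (isTRUE(params$algae)) {
    nalg <- 3L * npot
    ay <- stats::runif(nalg, y0 + 5, y1 - 5)
    ax <- stats::runif(nalg, x0 + 5, x1 - 5)
    for (i in seq_len(nalg)) {
      if (leaf_mask[round(ay[i]), round(ax[i])]) next
      idx <- disc_indices(ay[i], ax[i], stats::runif(1, 1.2, 2.2), H, W)
      nz <- stats::runif(length(idx), -10, 10)
      Rm[idx] <- 70 + nz; Gm[idx] <- 150 + nz; Bm[idx] <- 60 + nz
    }
  }

  px <- array(0, dim = c(H, W, 3))
  px[, , 1] <- Rm; px[, , 2] <- Gm; px[, , 3] <- Bm
  px <- pmax(pmin(px, 255), 0)
  pot_leaf_px <- vapply(seq_len(npot), function(i) {
    bb <- pot_bbox[[i]]
    sum(leaf_mask[bb[1]:bb[3], bb[2]:bb[4]])
  }, numeric(1))
  list(
    image = tray_image(px, source_name = sprintf("synthetic_seed%d", seed)),
    truth = list(
      leaf_mask = leaf_mask,
      pot_leaf_px = pot_leaf_px,
      pot_area_mm2 = pot_leaf_px / ppm^2,
      leaf_counts = ifelse(harvested, 0L, lc),
      harvested = harvested,
      markers = list(centres = mk, radius_px = params$marker_radius_px),
      px_per_mm = ppm,
      pot_bbox = pot_bbox,
      roi_bbox = c(y0, x0, y1, x1)
    )
  )
}

# Linear indices (column-major, H x W) of a filled disc.
disc_indices <- function(cy, cx, radius, H, W) {
  ys <- max(1, floor(cy - radius)):min(H, ceiling(cy + radius))
  xs <- max(1, floor(cx - radius)):min(W, ceiling(cx + radius))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  inside <- dy^2 + dx^2 <= radius^2
  as.vector(outer(ys, (xs - 1L) * H, `+`))[inside]
}

# Linear indices and centre distances of a rose-curve rosette
# r(theta) = L (0.6 + 0.4 cos(n theta - phase)).
rosette_indices <- function(cy, cx, L, n, phase, H, W) {
  ys <- max(1, floor(cy - L)):min(H, ceiling(cy + L))
  xs <- max(1, floor(cx - L)):min(W, ceiling(cx + L))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  d <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx)
  inside <- d <= L * (0.6 + 0.4 * cos(n * th - phase))
  list(idx = as.vector(outer(ys, (xs - 1L) * H, `+`))[inside],
       dist = d[inside])
}
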