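#' Tray layout
#'
#' @param rows,cols number of pot rows and columns in the tray (>= 1).
#' @return A `tray_layout` object.
#' @export
tray_layout <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("'rows' and 'cols' must be integers >= 1")
  structure(list(rows = rows, cols = cols), class = "tray_layout")
}

#' Partition the tray ROI into a pot lattice
#'
#' Cell boundaries fall at `round(i * W / cols)` and `round(j * H / rows)`,
#' so the pot rectangles tile the ROI exactly (pairwise disjoint, union
#' covering every pixel). Pots are indexed row-major: left to right, then
#' top to bottom.
#'
#' @param roi_shape integer vector `c(H, W)` of the ROI dimensions.
#' @param layout a [tray_layout()].
#' @return A list of `pot_region` objects, each with `index`, `row`, `col`
#'   and `bbox = c(y0, x0, y1, x1)` (1-based, inclusive).
#' @export
build_pot_layout <- function(roi_shape, layout) {
  stopifnot(inherits(layout, "tray_layout"))
  H <- roi_shape[1]; W <- roi_shape[2]
  if (H < layout$rows || W < layout$cols)
    stop("ROI smaller than the pot lattice")
  ys <- as.integer(round((0:layout$rows) * H / layout$rows))
  xs <- as.integer(round((0:layout$cols) * W / layout$cols))
  regions <- vector("list", layout$rows * layout$cols)
  for (r in seq_len(layout$rows)) {
    for (c in seq_len(layout$cols)) {
      idx <- (r - 1L) * layout$cols + c
      regions[[idx]] <- structure(
        list(index = idx, row = r, col = c,
             bbox = c(ys[r] + 1L, xs[c] + 1L, ys[r + 1L], xs[c + 1L])),
        class = "pot_region")
    }
  }
  regions
}

#' Split the global leaf mask into per-pot masks
#'
#' Each pot mask is the crop of the global mask to the pot's bounding box;
#' leaves crossing pot borders are clipped at the border, so the total
#' foreground pixel count is conserved across the split.
#'
#' @param mask a global `leaf_mask`.
#' @param regions pot regions from [build_pot_layout()].
#' @return A list of `pot_mask` objects (fields `region`, `mask`).
#' @export
split_into_pots <- function(mask, regions) {
  stopifnot(inherits(mask, "leaf_mask"))
  H <- nrow(mask$mask); W <- ncol(mask$mask)
  last <- regions[[length(regions)]]$bbox
  if (last[3] != H || last[4] != W)
    stop("mask dimensions do not match the pot layout")
  lapply(regions, function(rg) {
    bb <- rg$bbox
    structure(list(region = rg,
                   mask = mask$mask[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE]),
              class = "pot_mask")
  })
}

#' @export
print.pot_mask <- function(x, ...) {
  cat(sprintf("<pot_mask> pot %d (row %d, col %d): %d foreground px\n",
              x$region$index, x$region$row, x$region$col, sum(x$mask)))
  invisible(x)
}

#' Refine a pot mask by local feature selection
#'
#' Removes false-positive components (algae speckle, soil reflections,
#' fringes of neighbouring plants) from one pot's mask using local
#' intensity and positional rules:
#' * components smaller than `min_area_mm2` (1 mm^2 equivalent) are dropped;
#' * components whose mean greenness falls below the pot-level Otsu level of
#'   the `G_V` sub-image are dropped;
#' * of the survivors, a component is kept when its centroid lies in the
#'   central 90% of the pot or within 20% of the pot width of the largest
#'   surviving component.
#'
#' The surviving foreground is always a subset of the input; a fully removed
#' mask is a valid empty pot (e.g. destructively harvested).
#'
#' @param pot a `pot_mask`.
#' @param img the denoised [calibrated_image()] the mask refers to.
#' @param min_area_mm2 minimum component area in mm^2.
#' @return The refined `pot_mask`.
#' @export
refine_pot_mask <- function(pot, img, min_area_mm2 = 1) {
  stopifnot(inherits(pot, "pot_mask"), inherits(img, "calibrated_image"))
  m <- pot$mask
  if (!any(m > 0L)) return(pot)
  bb <- pot$region$bbox
  ppm <- img$scale$px_per_mm
  sub <- img$pixels[bb[1]:bb[3], bb[2]:bb[4], , drop = FALSE]
  gv <- compute_greenness_img(list(pixels = sub))$values
  labels <- label_mask(m)
  # area screening first, then intensity screening
  st <- component_stats(labels, min_area = min_area_mm2 * ppm^2,
                        shape = FALSE)
  if (nrow(st) > 0) {
    thr <- otsu_threshold(gv)
    mean_gv <- component_means(labels, gv, st$label)
    st <- st[mean_gv >= thr, , drop = FALSE]
  }
  if (nrow(st) > 1L) {
    # positional screening relative to the pot and the largest survivor
    H <- nrow(m); W <- ncol(m)
    central <- st$cy >= 0.05 * H & st$cy <= 0.95 * H &
      st$cx >= 0.05 * W & st$cx <= 0.95 * W
    big <- which.max(st$area)
    near <- sqrt((st$cy - st$cy[big])^2 + (st$cx - st$cx[big])^2) < 0.2 * W
    st <- st[central | near, , drop = FALSE]
  }
  out <- matrix(0L, nrow(m), ncol(m))
  out[labels %in% st$label] <- 1L
  structure(list(region = pot$region, mask = out), class = "pot_mask")
}
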