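# Shared fixture builders. Everything is generated in code; no files.

# A pot_mask wrapper around a plain binary matrix.
as_pot <- function(m, index = 1L) {
  storage.mode(m) <- "integer"
  structure(list(
    region = structure(list(index = index, row = 1L, col = 1L,
                            bbox = c(1L, 1L, nrow(m), ncol(m))),
                       class = "pot_region"),
    mask = m), class = "pot_mask")
}

disc_mask <- function(H, W, cy, cx, r) {
  m <- matrix(0L, H, W)
  yy <- row(m); xx <- col(m)
  m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 1L
  m
}

# Rose-curve mask r(theta) = base + amp * cos(n theta + phase).
rose_mask <- function(H, W, cy, cx, base, amp, n, phase = 0) {
  m <- matrix(0L, H, W)
  dy <- row(m) - cy; dx <- col(m) - cx
  d <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx)
  m[d <= base + amp * cos(n * th + phase)] <- 1L
  m
}

# A flat-colour image as a tray_image.
flat_image <- function(H, W, rgb) {
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  tray_image(px)
}

# Paint a disc of colour `rgb` onto a tray_image.
paint_disc <- function(img, cy, cx, r, rgb) {
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  d <- disc_mask(H, W, cy, cx, r) > 0
  for (ch in 1:3) {
    s <- img$pixels[, , ch]; s[d] <- rgb[ch]; img$pixels[, , ch] <- s
  }
  img
}

# Independent brute-force end-point oracle: scan every pixel and apply the
# four 2x3 / 3x2 hit-or-miss kernels literally (NA = don't care).
brute_force_endpoints <- function(sk) {
  H <- nrow(sk); W <- ncol(sk)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- sk
  kerns <- list(
    rbind(c(0, 0, 0), c(0, 1, 0), c(NA, NA, NA)),
    rbind(c(NA, NA, NA), c(0, 1, 0), c(0, 0, 0)),
    rbind(c(0, 0, NA), c(0, 1, NA), c(0, 0, NA)),
    rbind(c(NA, 0, 0), c(NA, 1, 0), c(NA, 0, 0)))
  hits <- NULL
  for (y in 1:H) for (x in 1:W) {
    if (sk[y, x] != 1L) next
    nb <- pad[y:(y + 2), x:(x + 2)]
    for (k in kerns) {
      sel <- !is.na(k)
      if (all(nb[sel] == k[sel])) {
        hits <- rbind(hits, c(x, y))
        break
      }
    }
  }
  if (is.null(hits))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  colnames(hits) <- c("x", "y")
  hits[order(hits[, "x"], hits[, "y"]), , drop = FALSE]
}

# Small synthetic tray written to disk as a series of PNGs following the
# naming convention; returns the directory.
write_synthetic_series <- function(dir, n_images = 3, rows = 2, cols = 2,
                                   seed = 11, exp_ref = "Exp1",
                                   tray_no = "T01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_images)) {
    p <- synthetic_tray_params(rows = rows, cols = cols, width = 810,
                               height = 640, marker_radius_px = 20,
                               leaf_counts = 4,
                               petal_radius_mm = 10 + 2 * i)
    g <- generate_synthetic_tray(p, seed = seed)  # same layout each day
    write_plant_image(g$image,
                      file.path(dir, sprintf("%s_%s_2024-03-%02d.png",
                                             exp_ref, tray_no, i)))
  }
  dir
}
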