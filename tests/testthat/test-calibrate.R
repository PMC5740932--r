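test_that("rescaling fixes the working height and preserves aspect ratio", {
  cases <- list(c(1944, 2592, 1365), c(2848, 4288, 1542), c(1024, 900, 900))
  for (cs in cases) {
    img <- tray_image(array(128, dim = c(cs[1], cs[2], 3)))
    out <- rescale_to_height(img, 1024L)
    expect_equal(dim(out$pixels)[1], 1024L)
    expect_equal(dim(out$pixels)[2], cs[3])
    # input untouched
    expect_equal(dim(img$pixels)[1:2], cs[1:2])
  }
  # size-idempotent
  img <- tray_image(array(10, dim = c(500, 700, 3)))
  once <- rescale_to_height(img)
  twice <- rescale_to_height(once)
  expect_identical(dim(once$pixels), dim(twice$pixels))
  expect_error(rescale_to_height(img, 0), "positive")
})

test_that("the red-marker pixel rule follows the multi-threshold definition", {
  expect_equal(marker_threshold(255, 0, 0), 1L)
  expect_equal(marker_threshold(100, 100, 100), 0L)  # fails r > 125
  expect_equal(marker_threshold(200, 160, 100), 0L)  # r - g = 40
  expect_equal(marker_threshold(126, 0, 224), 1L)
  expect_equal(marker_threshold(126, 0, 225), 0L)
  # invariant to the blue channel anywhere below 225
  b_sweep <- 0:224
  expect_true(all(marker_threshold(200, 50, b_sweep) == 1L))
  expect_true(all(marker_threshold(100, 50, b_sweep) == 0L))
})

test_that("marker detection keeps the four discs and rejects distractors", {
  img <- flat_image(600, 800, c(90, 90, 90))
  pos <- rbind(c(60, 60), c(60, 740), c(540, 740), c(540, 60))
  for (i in 1:4) img <- paint_disc(img, pos[i, 1], pos[i, 2], 20,
                                   c(230, 30, 30))
  mk <- detect_reference_markers(img)
  expect_s3_class(mk, "marker_set")
  expect_equal(nrow(mk$markers), 4L)
  expect_lt(abs(mk$mean_radius_px - 20) / 20, 0.05)

  # an 80 x 8 red bar fails the eccentricity/solidity screen
  bar <- img
  for (ch in 1:3) {
    s <- bar$pixels[, , ch]
    s[300:307, 360:439] <- c(230, 30, 30)[ch]
    bar$pixels[, , ch] <- s
  }
  mk2 <- detect_reference_markers(bar)
  expect_equal(nrow(mk2$markers), 4L)
  expect_lt(abs(mk2$mean_radius_px - 20) / 20, 0.05)

  expect_error(detect_reference_markers(flat_image(200, 200, c(60, 60, 60))),
               "found 0")
})

test_that("scale derivation divides the mean radius by the physical radius", {
  mk <- structure(list(markers = data.frame(cx = 1:4, cy = 1:4,
                                            radius = rep(20, 4)),
                       mean_radius_px = 20), class = "marker_set")
  expect_equal(compute_scale(mk, 4)$px_per_mm, 5)
  expect_equal(compute_scale(mk, 5)$px_per_mm, 4)   # wheat preset
  expect_error(compute_scale(mk, 0), "positive")
})

test_that("scale recovery from rendered discs is within 5% across radii", {
  for (r in c(10, 20, 40)) {
    img <- flat_image(600, 800, c(90, 90, 90))
    pos <- rbind(c(80, 80), c(80, 720), c(520, 720), c(520, 80))
    for (i in 1:4) img <- paint_disc(img, pos[i, 1], pos[i, 2], r,
                                     c(230, 30, 30))
    sc <- compute_scale(detect_reference_markers(img), 4)
    expect_lt(abs(sc$px_per_mm - r / 4) / (r / 4), 0.05)
  }
})

test_that("ROI extraction crops axis-aligned marker rectangles exactly", {
  img <- flat_image(600, 800, c(90, 90, 90))
  pos <- rbind(c(100, 100), c(100, 700), c(500, 700), c(500, 100))
  for (i in 1:4) img <- paint_disc(img, pos[i, 1], pos[i, 2], 15,
                                   c(230, 30, 30))
  # distinctive pixel inside the rectangle
  img$pixels[300, 400, ] <- c(1, 2, 3)
  mk <- detect_reference_markers(img)
  roi <- extract_tray_roi(img, mk, image_scale(3.75))
  expect_lte(abs(dim(roi$pixels)[1] - 400), 1)
  expect_lte(abs(dim(roi$pixels)[2] - 600), 1)
  expect_s3_class(roi, "calibrated_image")
})

test_that("ROI extraction rectifies a rotated marker square", {
  side <- 300; ang <- 30 * pi / 180
  img <- flat_image(700, 700, c(90, 90, 90))
  for (s in list(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))) {
    x <- s[1] * side / 2; y <- s[2] * side / 2
    img <- paint_disc(img, 350 + x * sin(ang) + y * cos(ang),
                      350 + x * cos(ang) - y * sin(ang), 12, c(230, 30, 30))
  }
  mk <- detect_reference_markers(img)
  roi <- extract_tray_roi(img, mk, image_scale(3))
  expect_lte(abs(dim(roi$pixels)[1] - side), 1)
  expect_lte(abs(dim(roi$pixels)[2] - side), 1)
})

test_that("ROI extraction demands four non-degenerate markers", {
  mk3 <- structure(list(markers = data.frame(cx = c(1, 50, 1),
                                             cy = c(1, 1, 50),
                                             radius = rep(5, 3)),
                        mean_radius_px = 5), class = "marker_set")
  img <- flat_image(100, 100, c(50, 50, 50))
  expect_error(extract_tray_roi(img, mk3, image_scale(1)), "4 markers")
  mk_bad <- structure(list(markers = data.frame(cx = c(10, 20, 30, 40),
                                                cy = c(10, 10, 10, 10),
                                                radius = rep(5, 4)),
                           mean_radius_px = 5), class = "marker_set")
  expect_error(extract_tray_roi(img, mk_bad, image_scale(1)), "degenerate")
})

test_that("marker-bounded distances survive the full calibration within 2%", {
  p <- synthetic_tray_params(rows = 2, cols = 2, width = 1296, height = 972,
                             marker_radius_px = 22)
  g <- generate_synthetic_tray(p, seed = 9)
  work <- rescale_to_height(g$image)
  mk <- detect_reference_markers(work)
  sc <- compute_scale(mk, 4)
  roi <- extract_tray_roi(work, mk, sc)
  # horizontal marker-to-marker distance in mm, from the generator
  truth_mm <- (g$truth$markers$centres[2, 2] -
                 g$truth$markers$centres[1, 2]) / g$truth$px_per_mm
  measured_mm <- dim(roi$pixels)[2] / sc$px_per_mm
  expect_lt(abs(measured_mm - truth_mm) / truth_mm, 0.02)
})

test_that("denoising smooths speckle without changing geometry", {
  sc <- image_scale(3)
  flat <- calibrated_image(array(120, dim = c(200, 180, 3)), sc)
  out <- denoise(flat)
  expect_identical(dim(out$pixels), dim(flat$pixels))
  expect_lt(max(abs(out$pixels - flat$pixels)), 2)  # unchanged up to rounding

  set.seed(4)
  noisy <- flat
  salt <- matrix(runif(200 * 180) < 0.05, 200, 180)
  for (ch in 1:3) {
    s <- noisy$pixels[, , ch]; s[salt] <- 255; noisy$pixels[, , ch] <- s
  }
  sm <- denoise(noisy)
  inner <- function(a) a[20:180, 20:160, 2]
  expect_lt(stats::var(as.vector(inner(sm$pixels))),
            stats::var(as.vector(inner(noisy$pixels))))
  expect_equal(sm$scale$px_per_mm, 3)
})
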