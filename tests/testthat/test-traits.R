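test_that("projected area converts pixel counts through the scale", {
  sc5 <- image_scale(5)
  m <- matrix(0L, 50, 50); m[1:10, 1:10] <- 1L
  expect_equal(projected_leaf_area(as_pot(m), sc5), 100 / 25)
  expect_equal(projected_leaf_area(as_pot(matrix(0L, 10, 10)), sc5), 0)
  disc <- as_pot(disc_mask(120, 120, 60, 60, 50))
  expect_lt(abs(projected_leaf_area(disc, image_scale(1)) - pi * 2500) /
              (pi * 2500), 0.01)
})

test_that("perimeter follows the enclosing contours and is additive", {
  sc <- image_scale(1)
  sq <- matrix(0L, 120, 120); sq[11:110, 11:110] <- 1L
  expect_lt(abs(leaf_perimeter(as_pot(sq), sc) - 400) / 400, 0.02)
  expect_equal(leaf_perimeter(as_pot(matrix(0L, 10, 10)), sc), 0)
  d1 <- disc_mask(200, 200, 50, 50, 25)
  d2 <- disc_mask(200, 200, 140, 140, 30)
  expect_equal(leaf_perimeter(as_pot(d1 + d2), sc),
               leaf_perimeter(as_pot(d1), sc) + leaf_perimeter(as_pot(d2), sc))
})

test_that("daily RGR follows the normalised log-ratio definition", {
  expect_equal(daily_rgr(exp(2), exp(3), 1), 0.5)
  expect_equal(daily_rgr(123.4, 123.4, 3), 0)
  expect_true(is.na(daily_rgr(1, 50, 1)))      # ln(area1) = 0 singularity
  expect_error(daily_rgr(10, 20, 0), "positive")
  expect_error(daily_rgr(-1, 20, 1), "positive")
  # sign matches growth direction when ln(area1) > 0
  expect_gt(daily_rgr(10, 20, 2), 0)
  expect_lt(daily_rgr(20, 10, 2), 0)
})

test_that("convex hull metrics behave on discs, pairs and empty pots", {
  sc <- image_scale(1)
  disc <- as_pot(disc_mask(200, 200, 100, 100, 80))
  hm <- convex_hull_metrics(disc, sc)
  a <- projected_leaf_area(disc, sc)
  expect_lt(abs(hm$hull_area_mm2 / a - 1), 0.02)
  expect_gte(hm$hull_area_mm2, a)
  expect_lt(abs(hm$hull_length_mm - 161) / 161, 0.02)
  expect_lte(hm$hull_width_mm, hm$hull_length_mm)

  two <- matrix(0L, 50, 150); two[25, 25] <- 1L; two[25, 125] <- 1L
  hm2 <- convex_hull_metrics(as_pot(two), sc)
  expect_lt(abs(hm2$hull_length_mm - 100) / 100, 0.02)

  hm0 <- convex_hull_metrics(as_pot(matrix(0L, 20, 20)), sc)
  expect_equal(hm0$hull_area_mm2, 0)
  expect_equal(hm0$hull_length_mm, 0)
  expect_equal(sum(hm0$hull_mask), 0L)
})

test_that("stockiness scores shapes by circularity of the hull", {
  # circle: area = pi R^2 gives exactly 100
  expect_equal(stockiness(pi * 50^2, 100), 100)
  # square of side s: R = s * sqrt(2) / 2 -> 200 / pi
  s <- 10
  expect_equal(stockiness(s^2, s * sqrt(2)), 200 / pi, tolerance = 1e-10)
  # near-degenerate line
  sc <- image_scale(1)
  line <- matrix(0L, 20, 120); line[10, 11:110] <- 1L
  hm <- convex_hull_metrics(as_pot(line), sc)
  expect_lt(stockiness(projected_leaf_area(as_pot(line), sc),
                       hm$hull_length_mm), 5)
  expect_equal(stockiness(10, 0), 0)
})

test_that("compactness matches a brute-force hull-area oracle on a cross", {
  m <- matrix(0L, 41, 41)
  m[17:25, 3:39] <- 1L
  m[3:39, 17:25] <- 1L
  sc <- image_scale(1)
  hm <- convex_hull_metrics(as_pot(m), sc)
  meas <- compactness(projected_leaf_area(as_pot(m), sc), hm$hull_area_mm2)
  # oracle: dense sub-pixel grid classified against the corner hull
  idx <- which(m > 0L)
  pts <- cbind(x = (idx - 1) %/% 41 + 1, y = (idx - 1) %% 41 + 1)
  corners <- rbind(cbind(pts[, 1] - .5, pts[, 2] - .5),
                   cbind(pts[, 1] + .5, pts[, 2] - .5),
                   cbind(pts[, 1] - .5, pts[, 2] + .5),
                   cbind(pts[, 1] + .5, pts[, 2] + .5))
  hull <- corners[grDevices::chull(corners), ]
  sgn <- sum(hull[, 1] * hull[c(2:nrow(hull), 1), 2] -
               hull[c(2:nrow(hull), 1), 1] * hull[, 2])
  if (sgn < 0) hull <- hull[nrow(hull):1, ]   # force counter-clockwise
  step <- 0.05
  gx <- seq(0.5, 41.5, by = step); gy <- seq(0.5, 41.5, by = step)
  gpx <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  nh <- nrow(hull)
  inside <- rep(TRUE, nrow(gpx))
  for (i in seq_len(nh)) {      # convex polygon: all cross products one-sided
    j <- if (i == nh) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    v <- cbind(gpx[, 1] - hull[i, 1], gpx[, 2] - hull[i, 2])
    inside <- inside & (e[1] * v[, 2] - e[2] * v[, 1] >= -1e-9)
  }
  oracle_hull_area <- sum(inside) * step^2
  oracle <- 100 * sum(m) / oracle_hull_area
  expect_lt(abs(meas - oracle), 0.5)

  # convex shape reads ~100%
  disc <- as_pot(disc_mask(160, 160, 80, 80, 60))
  hmd <- convex_hull_metrics(disc, sc)
  expect_gt(compactness(projected_leaf_area(disc, sc), hmd$hull_area_mm2), 97)
  expect_equal(compactness(50, 100), 50)
  expect_equal(compactness(0, 0), 0)
})

test_that("metric outputs scale correctly with the pixel density", {
  m <- rose_mask(150, 150, 75, 75, 40, 20, 6)
  p <- as_pot(m)
  s1 <- image_scale(2); s2 <- image_scale(4)
  expect_equal(projected_leaf_area(p, s1) / 4, projected_leaf_area(p, s2))
  expect_equal(leaf_perimeter(p, s1) / 2, leaf_perimeter(p, s2))
  h1 <- convex_hull_metrics(p, s1); h2 <- convex_hull_metrics(p, s2)
  expect_equal(h1$hull_area_mm2 / 4, h2$hull_area_mm2)
  expect_equal(h1$hull_length_mm / 2, h2$hull_length_mm)
  expect_equal(h1$hull_width_mm / 2, h2$hull_width_mm)
})

test_that("isoperimetric lower bound holds across random shapes", {
  set.seed(31)
  sc <- image_scale(1)
  for (i in 1:8) {
    n <- sample(3:8, 1)
    m <- rose_mask(160, 160, 80, 80, runif(1, 30, 50), runif(1, 5, 25), n,
                   runif(1, 0, 2 * pi))
    a <- projected_leaf_area(as_pot(m), sc)
    per <- leaf_perimeter(as_pot(m), sc)
    expect_gte(per, 2 * sqrt(pi * a) * 0.95)
    hm <- convex_hull_metrics(as_pot(m), sc)
    expect_gte(hm$hull_area_mm2, a)
    expect_lte(compactness(a, hm$hull_area_mm2), 100)
    expect_lte(stockiness(a, hm$hull_length_mm), 100)
  }
})

test_that("greenness averages clipped G_V over the hull region", {
  img <- list(pixels = array(0, dim = c(40, 40, 3)))
  img$pixels[, , 2] <- 255                      # pure green: clipped 255
  full <- matrix(1L, 40, 40)
  expect_equal(greenness_mean(img, full), 255)
  black <- list(pixels = array(0, dim = c(40, 40, 3)))
  expect_equal(greenness_mean(black, full), 0)
  half <- list(pixels = array(0, dim = c(40, 40, 3)))
  half$pixels[1:20, , 2] <- 255
  expect_equal(greenness_mean(half, full), 127.5)
  expect_equal(greenness_mean(img, matrix(0L, 40, 40)), 0)
})
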