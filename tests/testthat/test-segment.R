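test_that("vegetative greenness follows ExG - ExR with clipping", {
  gv_of <- function(rgb) {
    img <- flat_image(2, 2, rgb)
    compute_greenness_img(img)$values[1, 1]
  }
  expect_equal(gv_of(c(0, 255, 0)), 255)   # raw 510, clipped
  expect_equal(gv_of(c(0, 0, 0)), 0)
  expect_equal(gv_of(c(255, 0, 0)), 0)     # raw -612, clipped
  expect_equal(gv_of(c(50, 100, 80)), 2 * 100 - 2.4 * 50)

  # monotone: non-decreasing in g, non-increasing in r (pre-clip regime)
  g_sweep <- vapply(seq(60, 200, by = 10),
                    function(g) gv_of(c(80, g, 60)), numeric(1))
  expect_true(all(diff(g_sweep) >= 0))
  r_sweep <- vapply(seq(10, 100, by = 10),
                    function(r) gv_of(c(r, 180, 60)), numeric(1))
  expect_true(all(diff(r_sweep) <= 0))
})

test_that("the midpoint sample rule picks floor((n+1)/2)", {
  expect_equal(select_sample_image(as.list(1:10)), 5)
  expect_equal(select_sample_image(as.list(1:9)), 5)
  expect_equal(select_sample_image(list("only")), "only")
  expect_error(select_sample_image(list()), "empty")
})

test_that("colour-group estimation censuses probe clusters and clamps", {
  px <- array(0, dim = c(100, 100, 3))
  cols <- list(c(200, 40, 40), c(40, 200, 40), c(40, 40, 200),
               c(200, 200, 40))
  blocks <- list(cbind(1:50, 1:50), cbind(1:50, 51:100),
                 cbind(51:100, 1:50), cbind(51:100, 51:100))
  for (i in 1:4) for (ch in 1:3)
    px[blocks[[i]][, 1], blocks[[i]][, 2], ch] <- cols[[i]][ch]
  img <- tray_image(px)
  expect_equal(estimate_colour_groups(img), 4L)

  # two flat colours -> rule yields 2 -> clamped to the minimum of 3
  px2 <- array(0, dim = c(100, 100, 3)); px2[1:50, , ] <- 200
  expect_equal(estimate_colour_groups(tray_image(px2)), 3L)

  # deterministic under the fixed seed
  p <- synthetic_tray_params(rows = 1, cols = 1, width = 600, height = 500,
                             marker_radius_px = 18, leaf_counts = 5)
  g <- generate_synthetic_tray(p, seed = 3)
  expect_identical(estimate_colour_groups(g$image),
                   estimate_colour_groups(g$image))

  # user overrides are clamped to [3, 10]
  expect_equal(clustering_config(k = 15)$k, 10L)
  expect_equal(clustering_config(k = 1)$k, 3L)
})

test_that("k-means mask isolates the high-greenness cluster", {
  gv <- structure(list(values = disc_mask(120, 120, 60, 60, 30) * 255,
                       clip_range = c(0, 255)), class = "greenness_image")
  mk <- kmeans_leaf_mask(gv, 3)
  expect_identical(mk$mask, disc_mask(120, 120, 60, 60, 30))

  gv0 <- structure(list(values = matrix(0, 50, 50), clip_range = c(0, 255)),
                   class = "greenness_image")
  expect_equal(sum(kmeans_leaf_mask(gv0, 3)$mask), 0L)
  expect_error(kmeans_leaf_mask(gv, 2), "must lie")

  # Otsu on a perfectly bimodal greenness image separates it exactly
  thr <- phenotray:::otsu_threshold(gv$values)
  expect_true(thr > 0 && thr < 255)
  expect_identical((gv$values > thr) * 1L,
                   disc_mask(120, 120, 60, 60, 30) * 1L)
})

test_that("generated rosettes are recovered by both global routes", {
  p <- synthetic_tray_params(rows = 1, cols = 2, width = 800, height = 500,
                             marker_radius_px = 20, leaf_counts = c(5, 7),
                             algae = FALSE)
  g <- generate_synthetic_tray(p, seed = 21)
  truth <- g$truth$leaf_mask
  gv <- compute_greenness_img(g$image)
  km <- kmeans_leaf_mask(gv, 4)
  expect_gt(sum(km$mask & truth) / sum(truth), 0.95)
  lb <- lab_leaf_mask(g$image)
  expect_gt(sum(lb$mask & truth) / sum(truth), 0.95)

  # fused mask never loses recall relative to either route
  comb <- combine_masks(km, lb, min_area_px = 0)
  rec <- function(m) sum(m & truth) / sum(truth)
  expect_gte(rec(comb$mask), max(rec(km$mask), rec(lb$mask)))
})

test_that("Lab opponent route is green-specific and catches tiny leaves", {
  img <- flat_image(80, 80, c(120, 120, 120))
  img <- paint_disc(img, 40, 40, 20, c(30, 180, 40))
  lm <- lab_leaf_mask(img)
  expect_identical(lm$mask, disc_mask(80, 80, 40, 40, 20))

  set.seed(8)
  grey <- matrix(runif(6400, 0, 255), 80, 80)
  gimg <- tray_image(array(rep(grey, 3), dim = c(80, 80, 3)))
  expect_lt(mean(lab_leaf_mask(gimg)$mask), 0.01)

  # tiny (<= 20 px) green spots on soil are present in the Lab mask
  soil <- flat_image(120, 120, c(116, 86, 60))
  for (ctr in list(c(30, 30), c(60, 90), c(95, 50)))
    soil <- paint_disc(soil, ctr[1], ctr[2], 2.2, c(46, 138, 52))
  tiny <- disc_mask(120, 120, 30, 30, 2.2) | disc_mask(120, 120, 60, 90, 2.2) |
    disc_mask(120, 120, 95, 50, 2.2)
  lm2 <- lab_leaf_mask(soil)
  expect_gt(sum(lm2$mask & tiny) / sum(tiny), 0.8)
})

test_that("the in-package Lab transform matches grDevices::convertColor", {
  set.seed(2)
  rgb <- matrix(runif(300, 0, 255), ncol = 3)
  ours <- phenotray:::rgb_to_lab_a(rgb[, 1], rgb[, 2], rgb[, 3])
  ref <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab",
                                 scale.in = 255)[, 2]
  expect_lt(max(abs(ours - ref)), 0.5)
})

test_that("mask fusion is a union with small-object removal", {
  a <- leaf_mask(disc_mask(100, 100, 30, 30, 10))
  b <- leaf_mask(disc_mask(100, 100, 70, 70, 10))
  u <- combine_masks(a, b)
  expect_identical(u$mask, pmax(a$mask, b$mask))

  empty <- leaf_mask(matrix(0L, 100, 100))
  expect_identical(combine_masks(empty, b)$mask, b$mask)

  # commutative for random masks
  set.seed(5)
  for (i in 1:5) {
    x <- leaf_mask(matrix(as.integer(runif(900) < 0.3), 30, 30))
    y <- leaf_mask(matrix(as.integer(runif(900) < 0.3), 30, 30))
    expect_identical(combine_masks(x, y, 4)$mask, combine_masks(y, x, 4)$mask)
  }

  # min-area removal drops specks but keeps large objects
  spk <- leaf_mask(disc_mask(100, 100, 20, 80, 1))
  u2 <- combine_masks(a, spk, min_area_px = 10)
  expect_identical(u2$mask, a$mask)

  expect_error(combine_masks(a, leaf_mask(matrix(0L, 10, 10))), "dimensions")
})
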