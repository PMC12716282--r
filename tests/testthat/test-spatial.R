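make_grid <- function(values, xlim = c(0, 1), ylim = c(0, 1), group = "g") {
  structure(list(values = values,
                 x = seq(xlim[1], xlim[2], length.out = ncol(values)),
                 y = seq(ylim[1], ylim[2], length.out = nrow(values)),
                 xlim = xlim, ylim = ylim, trait = "t", group = group,
                 n_wings = 1L),
            class = "asymmetry_grid")
}

test_that("per-cell asymmetry is zero for a symmetric pair", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  pa <- pair_asymmetry(pair$left, pair$right, keep = "full")
  for (trait in c("circularity", "centroid")) {
    p <- per_cell_asymmetry(pa, trait)
    expect_equal(max(abs(p$value)), 0)
  }
})

test_that("per-cell percent difference averages both directions", {
  # circularity 0.8 vs 0.72: mean(8/0.8, 8/0.72) percent = 10.5555...
  feats <- function(circ) data.frame(cell_id = 1, area = 1, perimeter = 1,
                                     length = 1, width = 1, circularity = circ,
                                     centroid_x = 0, centroid_y = 0,
                                     set_label = NA_integer_)
  map <- list(cells = data.frame(from = "1", to = "1", dist = 0))
  pa <- list(map_lr = map, map_rl = map,
             feats_l = feats(0.8), feats_r = feats(0.72))
  p <- per_cell_asymmetry(pa, "circularity")
  expect_equal(p$value, mean(c(0.08 / 0.8, 0.08 / 0.72)) * 100,
               tolerance = 1e-12)
})

test_that("a rigid offset appears as a constant centroid distance", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  al <- align_pair(pair$left, pair$right)
  al$right$junctions$x <- al$right$junctions$x + 10
  for (i in seq_along(al$right$cells))
    al$right$cells[[i]]$vertices[, 1] <- al$right$cells[[i]]$vertices[, 1] + 10
  pa <- list(aligned = al,
             map_lr = match_sisters(al, "LR"), map_rl = match_sisters(al, "RL"),
             feats_l = cell_features_table(al$left),
             feats_r = cell_features_table(al$right))
  p <- per_cell_asymmetry(pa, "centroid")
  expect_equal(range(p$value), c(10, 10), tolerance = 1e-6)
})

test_that("the common frame is recovered for transformed wings", {
  pair <- generate_wing_pair(noise_free_config(seed = 6), 1)
  w <- pair$left
  tf0 <- superimpose_common_frame(list(w))[[1]]
  canon <- apply_frame_transform(w$outline, tf0)
  # already-canonical wing: near-identity transform
  w2 <- w; w2$outline <- canon
  tf_id <- superimpose_common_frame(list(w2))[[1]]
  expect_lt(abs(tf_id$theta), 1e-6)
  expect_lt(max(abs(tf_id$shift)), 1e-6)
  # rotated + shifted wing maps back onto the canonical pose
  w3 <- w
  w3$outline <- sweep(rotate_shape(canon, 7 * pi / 180), 2, -c(500, 300))
  tf3 <- superimpose_common_frame(list(w3))[[1]]
  back <- apply_frame_transform(w3$outline, tf3)
  expect_lt(abs(tf3$theta + 7 * pi / 180), 0.1 * pi / 180)
  expect_lt(max(abs(back - canon)), 25)
})

test_that("group grids reproduce constant and affine fields", {
  set.seed(12)
  pts <- data.frame(x = runif(120), y = runif(120))
  const <- transform(pts, value = 3.5)
  g <- build_group_grid(list(const), grid_n = 60)
  inside <- is.finite(g$values)
  expect_gt(mean(inside), 0.5)
  expect_lt(max(abs(g$values[inside] - 3.5)), 1e-9)
  ramp <- transform(pts, value = 2 * pts$x - 0.5 * pts$y + 1)
  g2 <- build_group_grid(list(ramp), grid_n = 60)
  xs <- matrix(rep(g2$x, each = nrow(g2$values)), nrow(g2$values))
  ys <- matrix(rep(g2$y, ncol(g2$values)), nrow(g2$values))
  ok <- is.finite(g2$values)
  expect_lt(max(abs(g2$values[ok] - (2 * xs[ok] - 0.5 * ys[ok] + 1))), 1e-6)
})

test_that("grids are invariant to the order of wings", {
  set.seed(3)
  wings <- lapply(1:4, function(i)
    data.frame(x = runif(40), y = runif(40), value = rnorm(40)))
  ext <- list(xlim = c(0, 1), ylim = c(0, 1))
  g1 <- build_group_grid(wings, grid_n = 40, extent = ext)
  g2 <- build_group_grid(rev(wings), grid_n = 40, extent = ext)
  expect_equal(g1$values, g2$values, tolerance = 1e-12)
})

test_that("the pooled trim suppresses extreme contamination", {
  set.seed(9)
  pts <- data.frame(x = runif(300), y = runif(300))
  clean <- transform(pts, value = rnorm(300, 10, 1))
  dirty <- clean
  idx <- sample(300, 15)
  dirty$value[idx] <- dirty$value[idx] * 100
  ext <- list(xlim = c(0, 1), ylim = c(0, 1))
  g_clean <- build_group_grid(list(clean), grid_n = 50, extent = ext)
  g_trim <- build_group_grid(list(dirty), trim = TRUE, grid_n = 50, extent = ext)
  m1 <- mean(g_clean$values, na.rm = TRUE)
  m2 <- mean(g_trim$values, na.rm = TRUE)
  expect_lt(abs(m2 - m1) / m1, 0.05)
})

test_that("difference maps subtract and blur as specified", {
  v <- matrix(rnorm(90 * 90), 90, 90)
  g1 <- make_grid(v); g2 <- make_grid(v, group = "h")
  d0 <- difference_map(g1, g2, blur_sigma = 0)
  expect_equal(max(abs(d0$values)), 0)
  expect_error(difference_map(g1, make_grid(v, xlim = c(0, 2))), "extent")
  # blur of a delta spike reproduces the Gaussian kernel profile
  z <- matrix(0, 121, 121); z[61, 61] <- 1
  b <- gaussian_blur_na(z, 10)
  xs <- -60:60
  k1 <- exp(-xs^2 / 200); k1 <- k1 / sum(k1)
  expected <- outer(k1, k1)
  rms <- sqrt(mean((b - expected)^2)) / max(expected)
  expect_lt(rms, 0.02)
})

test_that("the blur is missing-value aware", {
  z <- matrix(5, 80, 80)
  z[sample(6400, 2000)] <- NA  # ragged support
  b <- gaussian_blur_na(z, 6)
  ok <- is.finite(b)
  # mask normalization: a constant field stays exactly constant on support
  expect_lt(max(abs(b[ok] - 5)), 1e-9)
  # no extrapolation beyond the original support
  expect_true(all(is.na(b[is.na(z)])))
})
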