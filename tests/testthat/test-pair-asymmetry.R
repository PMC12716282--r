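test_that("NRMSE matches hand arithmetic and handles empty sets", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(1, 2), c(2, 1)), 1 / 1.5)
  # first-order behavior under uniform relative perturbation
  ref <- c(2, 3, 5, 7)
  for (eps in c(1e-3, 1e-5)) {
    expect_equal(nrmse(ref, ref * (1 + eps)),
                 eps * sqrt(mean(ref^2)) / mean(ref), tolerance = 1e-6)
  }
  expect_warning(v <- nrmse(numeric(0), numeric(0)), "empty")
  expect_true(is.na(v))
})

test_that("linear assignment equals brute-force enumeration", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, 0, 10), n, n)
    sol <- as.integer(clue::solve_LSAP(cost))
    oracle <- brute_lsap(cost)
    expect_equal(sum(cost[cbind(seq_len(n), sol)]), oracle$cost,
                 tolerance = 1e-12)
  }
})

test_that("alignment of an exact mirror is the identity", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  al <- align_pair(pair$left, pair$right)
  expect_equal(al$angle, 0)
  expect_lt(al$outline_distance, 1e-6)
})

test_that("alignment recovers a constructed 5-degree rotation", {
  pair <- generate_wing_pair(noise_free_config(seed = 5), 1)
  rot <- wingfa:::rotate_geometry(wingfa:::mirror_geometry(pair$left),
                                  5 * pi / 180)
  al <- align_pair(pair$left, rot)
  expect_lt(abs(abs(al$angle) - 5 * pi / 180), 0.1 * pi / 180)
  expect_lt(al$outline_distance, 1)
})

test_that("disjoint random blobs align without error but keep residual", {
  set.seed(8)
  a <- wing_from_cells(list(unit_square(100)),
                       outline = regular_polygon(12, 100))
  b <- wing_from_cells(list(unit_square(100)),
                       outline = regular_polygon(7, 60) +
                         matrix(rep(c(500, 300), each = 7), 7, 2))
  al <- align_pair(a, b)
  expect_gt(al$outline_distance, 10)
})

test_that("sister matching is perfect on identical mirrored wings", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  al <- align_pair(pair$left, pair$right)
  map <- match_sisters(al, "LR")
  expect_equal(nrow(map$cells), length(pair$left$cells))
  expect_equal(max(map$cells$dist), 0)
  expect_equal(length(map$unmatched_from), 0L)
  expect_true(all(map$cells$from == map$cells$to))
})

test_that("a removed cell leaves exactly one unmatched sister", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  right <- pair$right
  right$cells <- right$cells[-5]
  al <- align_pair(pair$left, right)
  map <- match_sisters(al, "LR")
  expect_equal(length(map$unmatched_from), 1L)
  expect_equal(length(map$unmatched_to), 0L)
})

test_that("matching recovers the ground-truth bijection under jitter", {
  # junction-channel jitter only: boundary cells keep a fixed outline, so
  # sister identity is well defined for every cell
  cfg <- synthetic_config(cells_target = 200, fa_position_sd_um = 20,
                          fa_shape_sd = 0, fa_outline_sd_um = 0,
                          count_perturb_prob = 0, size_cv = 0, seed = 1)
  hits <- 0L; total <- 0L
  for (i in 1:5) {
    p <- generate_wing_pair(cfg, i)
    al <- align_pair(p$left, p$right)
    map <- match_sisters(al, "LR")
    tid <- as.character(p$truth$cell_ids)
    to <- map$cells$to[match(tid, map$cells$from)]
    hits <- hits + sum(!is.na(to) & to == tid)
    total <- total + length(tid)
  }
  expect_gte(hits / total, 0.99)
})

test_that("the noise-free asymmetry record is exactly zero", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  rec <- pair_asymmetry(pair$left, pair$right)
  asym_vars <- c("nrmse_area", "nrmse_length", "nrmse_width",
                 "nrmse_circularity", "mean_dist_junctions",
                 "mean_dist_centroids", "mean_dist_outlines",
                 "subtract_cells", "subtract_junctions", "wing_area_diff",
                 "wing_perimeter_diff")
  expect_true(all(abs(unlist(rec[asym_vars])) <= 1e-9))
  wfl <- wing_features(pair$left)
  expect_equal(rec$wing_area, wfl$area / 1e6, tolerance = 1e-12)
  expect_equal(rec$n_cells, wfl$n_cells)
})

test_that("a rigid junction shift reads out as exactly that distance", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  al <- align_pair(pair$left, pair$right)
  al$right$junctions$x <- al$right$junctions$x + 10  # frozen alignment frame
  map_lr <- match_sisters(al, "LR")
  map_rl <- match_sisters(al, "RL")
  rec <- asymmetry_record(al, map_lr, map_rl)
  expect_equal(rec$mean_dist_junctions, 10, tolerance = 1e-9)
})

test_that("subtract values report absolute count differences", {
  polys <- lapply(1:6, function(i) unit_square(10) + cbind(rep(12 * i, 4), 0))
  a <- wing_from_cells(polys)
  b <- wing_from_cells(polys[1:3])
  al <- structure(list(left = a, right = b), class = "aligned_pair")
  map_lr <- match_sisters(al, "LR")
  map_rl <- match_sisters(al, "RL")
  rec <- asymmetry_record(al, map_lr, map_rl)
  expect_equal(rec$subtract_cells, 3)
})

test_that("the record is invariant to swapping the sides", {
  pair <- generate_wing_pair(quick_config(seed = 13), 1)
  r1 <- pair_asymmetry(pair$left, pair$right)
  mirrored_left <- wingfa:::mirror_geometry(pair$left)
  mirrored_right <- wingfa:::mirror_geometry(pair$right)
  r2 <- pair_asymmetry(mirrored_right, mirrored_left)
  for (v in c("nrmse_area", "nrmse_circularity", "mean_dist_junctions",
              "mean_dist_centroids", "subtract_cells", "wing_area_diff")) {
    expect_equal(r1[[v]], r2[[v]], tolerance = 1e-4)
  }
})

test_that("NRMSE variables are invariant to a global scale change", {
  pair <- generate_wing_pair(quick_config(seed = 17), 1)
  r1 <- pair_asymmetry(pair$left, pair$right)
  scale_geom <- function(g, s) {
    g$outline <- g$outline * s
    g$cells <- lapply(g$cells, function(cl) { cl$vertices <- cl$vertices * s; cl })
    g$junctions$x <- g$junctions$x * s; g$junctions$y <- g$junctions$y * s
    g$landmarks <- g$landmarks * s
    g
  }
  r2 <- pair_asymmetry(scale_geom(pair$left, 2.5), scale_geom(pair$right, 2.5))
  for (v in c("nrmse_area", "nrmse_length", "nrmse_width", "nrmse_circularity")) {
    expect_equal(r1[[v]], r2[[v]], tolerance = 1e-6)
  }
  expect_equal(r2$mean_dist_junctions, 2.5 * r1$mean_dist_junctions,
               tolerance = 1e-6)
})

test_that("the moment-based normality test matches the reference values", {
  # reference statistics computed independently with scipy.stats
  x <- c(0.5, 1.2, -0.3, 2.2, -1.7, 0.8, -0.4, 1.1, 0.2, -0.9,
         1.5, -2.1, 0.3, 0.7, -0.6, 1.9, -1.2, 0.1, 0.9, -0.8,
         2.5, -1.4, 0.6, 0.4, -0.2)
  r <- dagostino_k2(x)
  expect_equal(r$z_skew, -0.033898656806957604, tolerance = 1e-10)
  expect_equal(r$z_kurt, -0.39706914322129877, tolerance = 1e-10)
  expect_equal(r$k2, 0.15881302343181217, tolerance = 1e-10)
  expect_equal(r$p_k2, 0.9236643677291092, tolerance = 1e-10)
})

test_that("symmetry-type screening flags DA and antisymmetry as designed", {
  expect_error(screen_symmetry_type(c(1, 2)), "at least 3")
  set.seed(31)
  n <- 100; reps <- 100
  null_da <- 0; null_anti <- 0; hit_da <- 0; hit_anti <- 0
  for (r in 1:reps) {
    d0 <- rnorm(n)
    s0 <- screen_symmetry_type(d0)
    null_da <- null_da + s0$directional_asymmetry
    null_anti <- null_anti + s0$antisymmetry
    s1 <- screen_symmetry_type(d0 + 3.5 / sqrt(n))  # clearly powered offset
    hit_da <- hit_da + s1$directional_asymmetry
    s2 <- screen_symmetry_type(sample(c(-1, 1), n, TRUE) + rnorm(n, 0, 0.25))
    hit_anti <- hit_anti + s2$antisymmetry
  }
  expect_gte(reps - null_da, 0.9 * reps)   # type-I control, mean-zero test
  expect_gte(reps - null_anti, 0.9 * reps) # type-I control, normality flag
  expect_gt(hit_da / reps, 0.8)            # power at the stated offset
  expect_gt(hit_anti / reps, 0.9)          # antisymmetry power
})
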