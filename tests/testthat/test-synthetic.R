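test_that("identical configurations produce identical cohorts", {
  cfg <- quick_config(n_individuals = 3L)
  a <- generate_cohort(cfg, data.frame(n = 3))
  b <- generate_cohort(cfg, data.frame(n = 3))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$pairs, b$pairs)
})

test_that("noise-free pairs are exact mirrors", {
  pair <- generate_wing_pair(noise_free_config(), 1)
  expect_identical(pair$left$outline[, 1], -pair$right$outline[, 1])
  expect_identical(pair$left$outline[, 2], pair$right$outline[, 2])
  expect_equal(length(pair$left$cells), length(pair$right$cells))
  expect_identical(pair$left$junctions$x, -pair$right$junctions$x)
})

test_that("forced merge removes exactly one cell on the requested side", {
  cfg <- noise_free_config()
  pair <- generate_wing_pair(cfg, 1, force_merge = "right")
  expect_equal(length(pair$left$cells) - length(pair$right$cells), 1L)
  ref <- generate_wing_pair(cfg, 1, force_merge = "none")
  expect_equal(length(pair$left$cells), length(ref$left$cells))
})

test_that("junction displacement follows the Rayleigh mean of two-sided jitter", {
  # difference of two independent per-axis jitters (sd 20 um each side):
  # E|D| = 20 * sqrt(2) * sqrt(pi / 2)
  cfg <- synthetic_config(cells_target = 200, fa_position_sd_um = 20,
                          fa_shape_sd = 0, count_perturb_prob = 0,
                          size_cv = 0, seed = 1)
  disp <- vapply(1:200, function(i) {
    p <- generate_wing_pair(cfg, i, detail = "counts")
    ids <- p$truth$junction_ids
    d <- p$truth$nodes_left[ids, , drop = FALSE] -
      p$truth$nodes_right[ids, , drop = FALSE]
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  expected <- 20 * sqrt(2) * sqrt(pi / 2)
  expect_lt(abs(mean(disp) - expected) / expected, 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(cells_target = 2))
  expect_error(synthetic_config(fa_position_sd_um = -1))
  expect_error(synthetic_config(count_perturb_prob = 1.5))
  expect_error(synthetic_config(effect_map = list(bti = c(outline_length_mm = -2))))
})

test_that("empty cohorts and empty designs behave per contract", {
  cfg <- quick_config(n_individuals = 0L)
  co <- generate_cohort(cfg, detail = "counts")
  expect_s3_class(co$cohort, "data.frame")
  expect_equal(nrow(co$cohort), 0L)
  expect_error(generate_cohort(cfg, data.frame()), "empty design")
})

test_that("effect multipliers scale the targeted parameter", {
  cfg <- synthetic_config(seed = 5, size_cv = 0.05,
                          effect_map = list(hydrology = c(outline_length_mm = 1.25)))
  co <- generate_cohort(cfg, data.frame(hydrology = c(0, 1), n = 40),
                        detail = "sizes")
  m <- tapply(co$cohort$wing_length, co$cohort$hydrology, mean)
  expect_lt(abs(m[["1"]] / m[["0"]] - 1.25), 0.03)
})

test_that("each wing carries 12 finite, distinct landmarks", {
  pair <- generate_wing_pair(quick_config(), 2)
  for (g in list(pair$left, pair$right)) {
    expect_equal(dim(g$landmarks), c(12, 2))
    expect_true(all(is.finite(g$landmarks)))
    expect_equal(nrow(unique(round(g$landmarks, 6))), 12)
  }
})

test_that("rendering a single square cell yields one interior component", {
  sq <- unit_square(400)
  w <- wing_from_cells(list(sq), outline = sq)
  img <- render_wing_image(w, scale_um_per_px = 10)
  interior <- EBImage::bwlabel((img > 0.5) * 1)
  # largest white region is the exterior; exactly one more inside
  expect_equal(max(interior), 2L)
})

test_that("a cell thinner than the vein stroke vanishes with a warning", {
  big <- matrix(c(0, 0, 400, 0, 400, 380, 0, 380), 4, 2, byrow = TRUE)
  thin <- matrix(c(0, 380, 400, 380, 400, 400, 0, 400), 4, 2, byrow = TRUE)
  outline <- matrix(c(0, 0, 400, 0, 400, 400, 0, 400), 4, 2, byrow = TRUE)
  w <- wing_from_cells(list(big, thin), outline = outline)
  expect_warning(img <- render_wing_image(w, scale_um_per_px = 10,
                                          vein_width_px = 5), "vanish")
  interior <- EBImage::bwlabel((img > 0.5) * 1)
  expect_equal(max(interior) - 1L, length(w$cells) - 1L)
})

test_that("counts and geometry detail agree on cell counts", {
  cfg <- quick_config(seed = 11)
  for (i in 1:3) {
    pg <- generate_wing_pair(cfg, i, detail = "geometry")
    pc <- generate_wing_pair(cfg, i, detail = "counts")
    expect_equal(length(pg$left$cells), pc$left$n_cells_truth)
    expect_equal(nrow(pg$left$junctions), nrow(pc$left$junctions))
  }
})

test_that("wing pairs tile the outline interior without gaps", {
  for (seed in c(3, 9)) {
    pair <- generate_wing_pair(noise_free_config(seed = seed), 1)
    cell_area <- sum(vapply(pair$left$cells,
                            function(cl) wingfa:::poly_area(cl$vertices),
                            numeric(1)))
    outline_area <- wingfa:::poly_area(pair$left$outline)
    expect_lt(abs(cell_area - outline_area) / outline_area, 1e-9)
  }
})
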