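test_that("GPA aligns similarity-transformed copies to one shape", {
  set.seed(42)
  base <- matrix(rnorm(24), 12, 2)
  shapes <- lapply(1:6, function(i) {
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.5, 2); tr <- rnorm(2, 0, 5)
    sweep(rotate_shape(base, th) * s, 2, -tr)
  })
  fit <- gpa(shapes)
  expect_true(fit$converged)
  spread <- max(apply(fit$aligned, c(1, 2), function(v) diff(range(v))))
  expect_lt(spread, 1e-8)
})

test_that("the two-shape consensus is Procrustes-equidistant from both", {
  set.seed(5)
  a <- matrix(rnorm(24), 12, 2)
  b <- a + matrix(rnorm(24, 0, 0.3), 12, 2)
  fit <- gpa(list(a, b))
  d <- apply(fit$aligned, 3, function(m) sqrt(sum((m - fit$consensus)^2)))
  expect_equal(d[1], d[2], tolerance = 1e-8)
})

test_that("single-configuration fits only center, scale and reflect", {
  a <- matrix(rnorm(24), 12, 2)
  fit <- gpa(list(a), reflect = TRUE)
  ref <- a; ref[, 1] <- -ref[, 1]
  ref <- sweep(ref, 2, colMeans(ref))
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(fit$aligned[, , 1], ref, tolerance = 1e-12)
})

test_that("collinear configurations are rejected", {
  line <- cbind(1:12, 2 * (1:12) + 3)
  expect_error(gpa(list(line, line)), "collinear|rank")
})

test_that("GPA rotation agrees with the vegan Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(7)
  a <- matrix(rnorm(24), 12, 2)
  b <- rotate_shape(a + matrix(rnorm(24, 0, 0.1), 12, 2), 0.7) * 1.4
  fit <- gpa(list(a, b))
  # residual misfit after our GPA must equal vegan's optimal superimposition
  va <- vegan::procrustes(fit$aligned[, , 1], fit$aligned[, , 2],
                          scale = FALSE, translation = FALSE)
  expect_lt(max(abs(va$rotation - diag(2))), 1e-6)
})

test_that("FA decomposition separates DA from individual FA", {
  n <- 10; k <- 12
  arr <- array(0, c(k, 2, 2 * n))
  ind <- rep(1:n, each = 2)
  side <- rep(c("left", "right"), n)
  # perfectly symmetric individuals: all scores zero
  dec0 <- fa_decomposition(arr + 1, ind, side)
  expect_true(all(dec0$scores$fa_score == 0))
  # identical constant L-R shift: absorbed by DA, all scores zero
  arr_da <- arr
  arr_da[3, 1, side == "left"] <- 0.05
  dec_da <- fa_decomposition(arr_da, ind, side)
  expect_true(all(abs(dec_da$scores$fa_score) < 1e-12))
  expect_equal(dec_da$da[3, 1], 0.05)
  # one displaced individual: delta*(n-1)/n for it, delta/n for the rest
  delta <- 0.01
  arr_fa <- arr
  arr_fa[4, 1, 1] <- delta
  dec <- fa_decomposition(arr_fa, ind, side)
  expect_equal(dec$scores$fa_score[1], delta * (n - 1) / n, tolerance = 1e-10)
  expect_equal(dec$scores$fa_score[-1], rep(delta / n, n - 1), tolerance = 1e-10)
  # FA components sum to zero by construction
  fa_sum <- apply(sweep(dec$asymmetry, c(1, 2), dec$da), c(1, 2), sum)
  expect_lt(max(abs(fa_sum)), 1e-12)
  # mean asymmetry equals the DA vector
  expect_equal(apply(dec$asymmetry, c(1, 2), mean), dec$da, tolerance = 1e-12)
})

test_that("individuals missing one side are dropped with a warning", {
  arr <- array(rnorm(12 * 2 * 5), c(12, 2, 5))
  ind <- c(1, 1, 2, 2, 3)
  side <- c("left", "right", "left", "right", "left")
  expect_warning(dec <- fa_decomposition(arr, ind, side), "missing")
  expect_equal(nrow(dec$scores), 2)
})

test_that("FA scores are invariant to global similarity transforms", {
  pairs <- lapply(1:6, function(i) generate_wing_pair(quick_config(seed = 23), i))
  lmt <- landmark_table(pairs, sex = rep(c("f", "m"), 3))
  s1 <- fa_scores(lmt)
  lmt2 <- lmt
  th <- 0.6; s <- 3.2; tr <- c(1000, -500)
  xy <- rotate_shape(cbind(lmt2$x, lmt2$y), th) * s
  lmt2$x <- xy[, 1] + tr[1]; lmt2$y <- xy[, 2] + tr[2]
  s2 <- fa_scores(lmt2)
  expect_equal(s1$fa_score, s2$fa_score, tolerance = 1e-8)
})

test_that("TPS and CSV landmark files round-trip", {
  pairs <- lapply(1:2, function(i) generate_wing_pair(quick_config(seed = 2), i))
  lmt <- landmark_table(pairs)
  tps <- tempfile(fileext = ".tps")
  write_landmarks_tps(lmt, tps)
  back <- read_landmarks_tps(tps)
  expect_equal(nrow(back), nrow(lmt))
  m1 <- back[order(back$individual, back$side, back$lm), c("x", "y")]
  m2 <- lmt[order(lmt$individual, lmt$side, lmt$lm), c("x", "y")]
  expect_equal(unlist(m1), unlist(m2), tolerance = 1e-8,
               ignore_attr = TRUE)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = lmt$individual, side = lmt$side,
                       lm_index = lmt$lm, x = lmt$x, y = lmt$y),
            csv, row.names = FALSE)
  back2 <- read_landmarks_csv(csv)
  expect_named(back2, c("individual", "side", "lm", "x", "y"))
  expect_equal(nrow(back2), nrow(lmt))
})
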