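test_that("gaussian fits recover exact linear data", {
  d <- data.frame(x = 1:10, y = 2 + 3 * (1:10))
  wg <- fit_glm("y", d, "x", gaussian())
  expect_equal(unname(coef(wg$model)), c(2, 3), tolerance = 1e-10)
  expect_lt(wg$deviance, 1e-20)
  expect_equal(wg$coefficients$stat_type[1], "t")
})

test_that("the intercept-only Poisson MLE is the log mean", {
  d <- data.frame(y = c(1, 2, 3))
  wg <- fit_glm("y", d, "1", poisson())
  expect_equal(unname(coef(wg$model)), log(2), tolerance = 1e-8)
  expect_equal(wg$coefficients$stat_type[1], "z")
})

test_that("GLM coefficients match brute-force OLS and IRLS oracles", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(30:60, 1)
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
    X <- cbind(1, x1, x2)
    yg <- drop(X %*% c(1, 0.5, -0.8)) + rnorm(n)
    dg <- data.frame(y = yg, x1 = x1, x2 = x2)
    wg <- fit_glm("y", dg, c("x1", "x2"), gaussian())
    expect_equal(unname(coef(wg$model)), ols_oracle(X, yg), tolerance = 1e-8)

    yp <- rpois(n, exp(drop(X %*% c(1, 0.3, 0.4))))
    dp <- data.frame(y = yp, x1 = x1, x2 = x2)
    wp <- fit_glm("y", dp, c("x1", "x2"), poisson())
    expect_equal(unname(coef(wp$model)), irls_poisson_oracle(X, yp),
                 tolerance = 1e-8)
  }
})

test_that("Poisson responses are validated", {
  d <- data.frame(y = c(-1, 2, 3))
  expect_error(fit_glm("y", d, "1", poisson()), "negative")
})

sim_mesocosm <- function(n_arm = 20, seed = 1, beta_bti = 0) {
  set.seed(seed)
  d <- expand.grid(bti = 0:1, hydrology = 0:1)[rep(1:4, each = n_arm), ]
  d$sex <- rep(c("f", "m"), length.out = nrow(d))
  d$y <- rnorm(nrow(d), 10 + beta_bti * d$bti + 0.5 * (d$sex == "m"), 1)
  d
}

test_that("Type-II LR tests match their deviance arithmetic", {
  d <- sim_mesocosm(seed = 3, beta_bti = 1)
  wg <- fit_glm("y", d, c("bti", "hydrology", "bti:hydrology", "sex"),
                gaussian())
  lr <- lr_chisq_tests(wg)
  expect_setequal(lr$term, c("bti", "hydrology", "sex", "bti:hydrology"))
  n <- nrow(d)
  rss <- function(f) sum(residuals(lm(f, data = d))^2)
  # main effect respecting marginality: tested without the interaction
  chi_bti <- n * log(rss(y ~ hydrology + sex) / rss(y ~ bti + hydrology + sex))
  expect_equal(lr$chisq[lr$term == "bti"], chi_bti, tolerance = 1e-8)
  chi_int <- n * log(rss(y ~ bti + hydrology + sex) /
                       rss(y ~ bti * hydrology + sex))
  expect_equal(lr$chisq[lr$term == "bti:hydrology"], chi_int, tolerance = 1e-8)
  expect_true(all(lr$df == 1))
  expect_true(all(lr$p >= 0 & lr$p <= 1))
})

test_that("Poisson LR tests agree with the car Type-II oracle", {
  skip_if_not_installed("car")
  set.seed(21)
  d <- sim_mesocosm(seed = 21)
  d$y <- rpois(nrow(d), exp(1 + 0.3 * d$bti))
  wg <- fit_glm("y", d, c("bti", "hydrology", "bti:hydrology", "sex"),
                poisson())
  lr <- lr_chisq_tests(wg)
  ca <- car::Anova(wg$model, type = "II", test.statistic = "LR")
  for (term in c("bti", "hydrology", "sex", "bti:hydrology")) {
    expect_equal(lr$chisq[lr$term == term],
                 ca[term, "LR Chisq"], tolerance = 1e-6)
  }
})

test_that("aliased terms are reported as such", {
  d <- sim_mesocosm(seed = 2)
  d$dup <- d$bti
  wg <- fit_glm("y", d, c("bti", "dup"), gaussian())
  expect_error(lr_chisq_tests(wg), "aliased")
})

test_that("permuted responses give uniform LR p-values", {
  d <- sim_mesocosm(n_arm = 15, seed = 8, beta_bti = 0)
  set.seed(99)
  ps <- vapply(1:200, function(i) {
    d$y <- sample(d$y)
    wg <- fit_glm("y", d, c("bti", "sex"), gaussian())
    lr_chisq_tests(wg)$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("percentage changes follow the prediction recipe", {
  d <- sim_mesocosm(seed = 4)
  d$y <- 10 + 2 * d$bti  # exact group means 10 and 12
  wg <- fit_glm("y", d, c("bti", "hydrology", "bti:hydrology", "sex"),
                gaussian())
  pc <- percentage_change(wg, "bti")
  expect_equal(pc$change_pct, 20, tolerance = 1e-8)
  # baseline against itself is exactly zero
  pc0 <- percentage_change(wg, "bti", levels = 0)
  expect_equal(pc0$change_pct, 0)
  # identical groups: near-zero change
  d2 <- sim_mesocosm(seed = 6)
  wg2 <- fit_glm("y", d2, c("bti", "sex"), gaussian())
  pc2 <- percentage_change(wg2, "bti")
  expect_lt(abs(pc2$change_pct), 10)
  expect_gt(pc2$se_pct, 0)
})

test_that("the delta-method SE matches the two-group closed form", {
  set.seed(77)
  n0 <- 25; n1 <- 35
  d <- data.frame(g = rep(0:1, c(n0, n1)))
  d$y <- rnorm(nrow(d), 10 + 2 * d$g, 1.5)
  wg <- fit_glm("y", d, "g", gaussian())
  pc <- percentage_change(wg, "g")
  # closed form: pct = 100*b/b0 with V = vcov of (b0, b)
  V <- vcov(wg$model)
  b0 <- coef(wg$model)[[1]]; b <- coef(wg$model)[[2]]
  grad <- 100 * c(-b / b0^2, 1 / b0)
  expect_equal(pc$se_delta_pct, sqrt(drop(grad %*% V %*% grad)),
               tolerance = 1e-8)
  # the ratio SE must exceed the contrast-only SE (baseline uncertainty)
  se_b_only <- 100 * sqrt(V[2, 2]) / b0
  expect_gt(pc$se_delta_pct, se_b_only)
})

test_that("log-link percentage change requires a positive baseline", {
  d <- data.frame(y = c(0, 0, 0, 0, 1, 2), g = rep(0:1, each = 3))
  wg <- fit_glm("y", d, "g", poisson())
  # baseline mean is ~0: percent change undefined
  expect_error(percentage_change(wg, "g"), "zero")
})

test_that("run_full_analysis enforces mode columns and family map", {
  d <- sim_mesocosm(seed = 5)
  names(d)[names(d) == "y"] <- "wing_area"
  d$n_cells <- rpois(nrow(d), 250)
  expect_error(run_full_analysis(d[, c("wing_area", "sex")], "mesocosm"),
               "requires columns")
  res <- run_full_analysis(d, "mesocosm",
                           responses = c("wing_area", "n_cells"))
  expect_s3_class(res, "stress_analysis")
  expect_equal(res$fits$n_cells$family, "poisson")
  expect_equal(res$fits$wing_area$family, "gaussian")
  expect_true(all(c("bti", "hydrology", "bti:hydrology", "sex") %in%
                    res$lr_tests$term))
  expect_warning(run_full_analysis(d, "mesocosm",
                                   responses = c("wing_area", "nope")),
                 "skipped")
  # insecticide mode needs a concentration column
  expect_error(run_full_analysis(d, "insecticide"), "concentration")
})

test_that("residual diagnostics summarize the visual checks", {
  d <- sim_mesocosm(seed = 10)
  wg <- fit_glm("y", d, c("bti", "sex"), gaussian())
  diag <- residual_diagnostics(wg)
  expect_gt(diag$qq_correlation, 0.97)
  expect_lt(abs(diag$scale_location_slope), 1)
})
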