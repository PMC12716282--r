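# GLM layer: per-response model fits, Type-II likelihood-ratio tests for
# the factorial stressor design, and model-predicted percentage changes
# with standard errors.

#' Family map for the standard response inventory
#'
#' Count responses (days until emergence, cell and junction counts, subtract
#' values) are modeled with a Poisson distribution and log link; all other
#' responses with a gaussian distribution and identity link.
#'
#' @param response Response column name.
#' @return A [stats::family] object.
#' @export
response_family <- function(response) {
  poisson_responses <- c("days_to_emergence", "n_cells", "n_junctions",
                         "subtract_cells", "subtract_junctions")
  if (response %in% poisson_responses) poisson(link = "log")
  else gaussian(link = "identity")
}

#' Fit one response GLM
#'
#' Thin, structured wrapper around [stats::glm()]: gaussian-identity or
#' Poisson-log fits with per-coefficient t tests (gaussian) or Wald z tests
#' (Poisson). Counts are validated for the Poisson family; rounding of the
#' pair-mean counts (x.5 values) is applied with a message-free `round()`
#' before fitting.
#'
#' @param response Response column name in `data`.
#' @param data Cohort data frame.
#' @param predictors Character vector of model terms (may include
#'   interactions, e.g. `"bti:hydrology"`).
#' @param family Optional [stats::family]; defaults to
#'   [response_family()]`(response)`.
#' @return A list of class `wing_glm`: `model` (the glm fit), `response`,
#'   `family`, `coefficients` (estimate, SE, statistic, p), `deviance`,
#'   `df_residual`, `converged`.
#' @export
fit_glm <- function(response, data, predictors, family = NULL) {
  stopifnot(response %in% names(data))
  if (is.null(family)) family <- response_family(response)
  d <- data
  if (family$family == "poisson") {
    d[[response]] <- round(d[[response]])
    if (any(d[[response]] < 0, na.rm = TRUE))
      stop("Poisson response '", response, "' has negative values")
  }
  f <- as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  fit <- glm(f, data = d, family = family)
  if (!fit$converged)
    warning("GLM for '", response, "' did not converge; result flagged")
  sm <- summary(fit)$coefficients
  stat_name <- if (family$family == "gaussian") "t" else "z"
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      statistic = sm[, 3], p = sm[, 4],
                      stat_type = stat_name, row.names = NULL)
  structure(list(model = fit, response = response, family = family$family,
                 coefficients = coefs, deviance = deviance(fit),
                 df_residual = df.residual(fit), converged = fit$converged),
            class = "wing_glm")
}

#' Type-II likelihood-ratio chi-square tests
#'
#' For each term, compares the deviance of the model without that term
#' against the relevant reference model, respecting marginality: main
#' effects are tested in the model without the interaction; the interaction
#' against the full model. Gaussian models use the fixed-scale deviance
#' convention `chi2 = n * log(RSS_reduced / RSS_full)`; Poisson models the
#' deviance difference.
#'
#' @param wg A `wing_glm` from [fit_glm()].
#' @return A data frame `term`, `chisq`, `df`, `p`.
#' @export
lr_chisq_tests <- function(wg) {
  fit <- wg$model
  trm <- terms(fit)
  labels <- attr(trm, "term.labels")
  if (!length(labels)) stop("model has no terms to test")
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("aliased coefficient(s) in the model (collinear terms): ",
         paste(bad, collapse = ", "))
  }
  order_ <- attr(trm, "order")

  dev_stat <- function(reduced, full) {
    if (wg$family == "gaussian") {
      n <- length(fitted(full))
      n * log(deviance(reduced) / deviance(full))
    } else {
      deviance(reduced) - deviance(full)
    }
  }
  resp_name <- deparse(formula(fit)[[2]])
  refit <- function(drop_terms) {
    keep <- setdiff(labels, drop_terms)
    f <- as.formula(paste(resp_name, "~",
                          if (length(keep)) paste(keep, collapse = " + ") else "1"))
    glm(f, data = fit$data, family = fit$family)
  }
  contains <- function(high, low) {
    all(strsplit(low, ":")[[1]] %in% strsplit(high, ":")[[1]])
  }

  rows <- lapply(seq_along(labels), function(i) {
    term <- labels[i]
    higher <- labels[order_ > order_[i] & vapply(labels, contains, logical(1), low = term)]
    full <- refit(higher)
    reduced <- refit(c(term, higher))
    df <- length(coef(full)) - length(coef(reduced))
    if (df == 0) stop("term '", term, "' is aliased (collinear with others)")
    chisq <- dev_stat(reduced, full)
    data.frame(term = term, chisq = chisq, df = df,
               p = pchisq(chisq, df, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Model-predicted percentage change relative to a baseline level
#'
#' Predicts the response for every observed covariate row with the target
#' factor set to each level (other covariates, including the remaining
#' factors, kept as observed, so level means are averaged over the levels
#' of the other factors). The percentage change of level `l` against the
#' baseline is `100 * (mean_l - mean_0) / mean_0`; its SE is the standard
#' deviation of the within-level predictions divided by the square root of
#' the number of predictions, scaled by the baseline mean.
#'
#' @param wg A `wing_glm`.
#' @param factor_name Design column to contrast.
#' @param baseline Baseline level (default: first sorted unique value).
#' @param levels Levels to contrast against the baseline (default: all
#'   non-baseline observed values).
#' @return A data frame `factor`, `level`, `baseline_mean`, `level_mean`,
#'   `change_pct`, `se_pct` (prediction-spread recipe: within-level SD of
#'   predictions over sqrt(n), scaled by the baseline mean), `se_delta_pct`
#'   (delta-method SE of the ratio estimate from the model's covariance —
#'   the estimator SE, accounting for baseline-mean uncertainty and its
#'   covariance with the contrast), `n_predictions`.
#' @export
percentage_change <- function(wg, factor_name, baseline = NULL, levels = NULL) {
  fit <- wg$model
  data <- fit$data
  stopifnot(factor_name %in% names(data))
  obs <- sort(unique(data[[factor_name]]))
  if (is.null(baseline)) baseline <- obs[1]
  if (is.null(levels)) levels <- setdiff(obs, baseline)

  trm <- stats::delete.response(terms(fit))
  design_at <- function(level) {
    nd <- data
    nd[[factor_name]] <- rep(level, nrow(nd))
    mf <- model.frame(trm, nd, xlev = fit$xlevels)
    model.matrix(trm, mf, contrasts.arg = fit$contrasts)
  }
  pred_at <- function(level) {
    nd <- data
    nd[[factor_name]] <- rep(level, nrow(nd))
    predict(fit, newdata = nd, type = "response")
  }
  # mean response and its gradient wrt the coefficients, per level
  mean_and_grad <- function(level) {
    X <- design_at(level)
    eta <- drop(X %*% coef(fit))
    list(m = mean(fit$family$linkinv(eta)),
         g = colMeans(fit$family$mu.eta(eta) * X))
  }
  V <- stats::vcov(fit)
  b0 <- mean_and_grad(baseline)
  p0 <- pred_at(baseline)
  m0 <- mean(p0)
  scale_ref <- mean(abs(predict(fit, type = "response"))) + 1e-300
  if (abs(m0) <= 1e-8 * scale_ref)
    stop("baseline mean is numerically zero / not positive; ",
         "percentage change undefined")
  rows <- lapply(levels, function(l) {
    pl <- pred_at(l)
    bl <- mean_and_grad(l)
    grad <- 100 * (bl$g / b0$m - b0$g * bl$m / b0$m^2)
    se_delta <- sqrt(drop(grad %*% V %*% grad))
    data.frame(factor = factor_name, level = l, baseline_mean = m0,
               level_mean = mean(pl),
               change_pct = 100 * (mean(pl) - m0) / m0,
               se_pct = 100 * sd(pl) / sqrt(length(pl)) / abs(m0),
               se_delta_pct = se_delta,
               n_predictions = length(pl))
  })
  do.call(rbind, rows)
}

#' Residual diagnostics summary
#'
#' QQ-based normality statistic (correlation of sorted deviance residuals
#' with normal quantiles) and the scale-location slope (linear trend of
#' sqrt(|standardized residuals|) against fitted values), mirroring the
#' visual checks usually applied to these models.
#'
#' @param wg A `wing_glm`.
#' @return A one-row data frame `qq_correlation`, `scale_location_slope`.
#' @export
residual_diagnostics <- function(wg) {
  r <- stats::residuals(wg$model, type = "deviance")
  n <- length(r)
  qq <- cor(sort(r), qnorm((seq_len(n) - 0.5) / n))
  sr <- sqrt(abs(scale(r)[, 1]))
  fv <- fitted(wg$model)
  sl <- if (var(fv) > 0) coef(lm(sr ~ fv))[[2]] else 0
  data.frame(qq_correlation = qq, scale_location_slope = sl)
}

# response inventories per mode
mode_responses <- function(mode) {
  common <- c("wet_weight_mg", "fa_score", "subtract_cells",
              "subtract_junctions", "wing_area", "wing_area_diff",
              "wing_length", "wing_perimeter", "wing_width", "n_cells",
              "n_junctions", "nrmse_area", "nrmse_length", "nrmse_width",
              "nrmse_circularity", "mean_dist_centroids",
              "mean_dist_junctions", "mean_dist_outlines", "wing_load")
  if (mode == "insecticide") c("days_to_emergence", "wet_weight_gain_mg", common)
  else common
}

#' Run the full per-response stressor analysis
#'
#' Fits every available response with the standard family map and the
#' mode's design: `insecticide` mode uses continuous concentration plus
#' sex (per-coefficient t/Wald tests); `mesocosm` mode uses the 2 x 2
#' Bti x hydrology factorial plus sex, with Type-II likelihood-ratio tests
#' and predicted percentage changes per stressor. A factor-coding switch
#' (`concentration_as_factor`) reproduces per-level contrasts of the
#' highest dose instead of a linear dose term.
#'
#' @param cohort Data frame with design columns (`concentration` or
#'   `bti`/`hydrology`), `sex`, and response columns.
#' @param mode `"insecticide"` or `"mesocosm"`.
#' @param responses Responses to fit; defaults to every available column of
#'   the standard inventory. Unknown names are skipped with a warning.
#' @param concentration_as_factor Treat concentration as an unordered
#'   factor (insecticide mode).
#' @param p_adjust `"none"` (default, matching the no-correction
#'   convention) or any [stats::p.adjust] method applied across responses
#'   per term.
#' @return A list of class `stress_analysis`: `fits` (named list of
#'   `wing_glm`), `coefficients`, `lr_tests` (mesocosm), `pct_changes`,
#'   `diagnostics` (tidy data frames), `mode`.
#' @export
run_full_analysis <- function(cohort, mode = c("insecticide", "mesocosm"),
                              responses = NULL,
                              concentration_as_factor = FALSE,
                              p_adjust = "none") {
  mode <- match.arg(mode)
  required <- if (mode == "insecticide") "concentration" else c("bti", "hydrology")
  missing_cols <- setdiff(c(required, "sex"), names(cohort))
  if (length(missing_cols))
    stop("mode '", mode, "' requires columns: ", paste(missing_cols, collapse = ", "))

  if (is.null(responses)) {
    responses <- intersect(mode_responses(mode), names(cohort))
  } else {
    unknown <- setdiff(responses, names(cohort))
    if (length(unknown)) {
      warning("unknown response column(s) skipped: ", paste(unknown, collapse = ", "))
      responses <- setdiff(responses, unknown)
    }
  }
  if (!length(responses)) stop("no response columns available")

  if (mode == "insecticide") {
    dat <- cohort
    if (concentration_as_factor) dat$concentration <- factor(dat$concentration)
    predictors <- c("concentration", "sex")
    contrast_factors <- "concentration"
  } else {
    dat <- cohort
    predictors <- c("bti", "hydrology", "bti:hydrology", "sex")
    contrast_factors <- c("bti", "hydrology")
  }

  fits <- list(); coefs <- list(); lrs <- list(); pcts <- list(); diags <- list()
  for (resp in responses) {
    ok <- complete.cases(dat[, c(resp, sub(":.*", "", predictors), "sex")])
    wg <- tryCatch(fit_glm(resp, dat[ok, , drop = FALSE], predictors),
                   error = function(e) {
                     warning("response '", resp, "' skipped: ", conditionMessage(e))
                     NULL
                   })
    if (is.null(wg)) next
    fits[[resp]] <- wg
    coefs[[resp]] <- cbind(response = resp, wg$coefficients)
    if (mode == "mesocosm") {
      lrs[[resp]] <- cbind(response = resp, lr_chisq_tests(wg))
    }
    pc <- lapply(contrast_factors, function(f)
      tryCatch(percentage_change(wg, f), error = function(e) NULL))
    pc <- do.call(rbind, pc[!vapply(pc, is.null, logical(1))])
    if (!is.null(pc)) pcts[[resp]] <- cbind(response = resp, pc)
    diags[[resp]] <- cbind(response = resp, residual_diagnostics(wg))
  }
  lr_tests <- if (length(lrs)) do.call(rbind, lrs) else NULL
  if (!is.null(lr_tests) && p_adjust != "none") {
    lr_tests$p_adjusted <- stats::ave(lr_tests$p, lr_tests$term,
                                      FUN = function(p) stats::p.adjust(p, p_adjust))
  }
  structure(list(fits = fits,
                 coefficients = do.call(rbind, coefs),
                 lr_tests = lr_tests,
                 pct_changes = if (length(pcts)) do.call(rbind, pcts) else NULL,
                 diagnostics = do.call(rbind, diags),
                 mode = mode),
            class = "stress_analysis")
}

#' @export
print.stress_analysis <- function(x, ...) {
  cat(sprintf("<stress_analysis> mode=%s, %d responses fitted\n",
              x$mode, length(x$fits)))
  if (!is.null(x$lr_tests)) {
    sig <- x$lr_tests[x$lr_tests$p < 0.05 & x$lr_tests$term != "sex", ]
    cat(sprintf("  %d significant stressor LR tests at alpha=0.05\n", nrow(sig)))
  }
  invisible(x)
}
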