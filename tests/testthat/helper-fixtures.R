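# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately naive (enumeration, hand algebra, textbook iterations) and
# never call the code paths they check.

quick_config <- function(...) {
  args <- list(...)
  defaults <- list(cells_target = 40L, seed = 7L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

noise_free_config <- function(seed = 3L, cells_target = 60L, ...) {
  synthetic_config(cells_target = cells_target, fa_position_sd_um = 0,
                   fa_shape_sd = 0, count_perturb_prob = 0, size_cv = 0,
                   seed = seed, ...)
}

unit_square <- function(s = 1) {
  matrix(c(0, 0, s, 0, s, s, 0, s), 4, 2, byrow = TRUE)
}

regular_polygon <- function(n, r = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(t), r * sin(t))
}

# wing_geometry built from a list of cell polygons (outline = bbox hull)
wing_from_cells <- function(polys, outline = NULL, side = "left",
                            junctions = NULL) {
  all_v <- do.call(rbind, polys)
  if (is.null(outline)) {
    xr <- range(all_v[, 1]); yr <- range(all_v[, 2])
    outline <- matrix(c(xr[1], yr[1], xr[2], yr[1], xr[2], yr[2], xr[1], yr[2]),
                      4, 2, byrow = TRUE)
  }
  if (is.null(junctions))
    junctions <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                            degree = integer(0))
  structure(list(side = side, wing_type = "front", outline = outline,
                 cells = lapply(seq_along(polys), function(i)
                   list(id = i, vertices = polys[[i]], set_label = NA_integer_)),
                 junctions = junctions, landmarks = NULL,
                 scale_um_per_px = NA_real_),
            class = "wing_geometry")
}

# raster of a clean rectangular lattice: ncx x ncy cells of cell_px pixels
lattice_image <- function(ncx, ncy, cell_px = 30, margin = 10) {
  w <- ncx * cell_px + 2 * margin + 1
  h <- ncy * cell_px + 2 * margin + 1
  img <- matrix(1, h, w)
  xs <- margin + seq(0, ncx) * cell_px + 1
  ys <- margin + seq(0, ncy) * cell_px + 1
  img[ys[1]:ys[ncy + 1], xs] <- 0
  img[ys, xs[1]:xs[ncx + 1]] <- 0
  attr(img, "scale_um_per_px") <- 1
  img
}

# brute-force linear assignment by permutation enumeration (n <= 7)
brute_lsap <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# textbook Newton-scoring IRLS for a Poisson log-link GLM
irls_poisson_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.1)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  unname(beta)
}

ols_oracle <- function(X, y) unname(drop(solve(crossprod(X), crossprod(X, y))))

# brute-force NRMSE with explicit loops
nrmse_oracle <- function(ref, other) {
  s <- 0
  for (i in seq_along(ref)) s <- s + (ref[i] - other[i])^2
  sqrt(s / length(ref)) / (sum(ref) / length(ref))
}
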