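# Spatial asymmetry maps: per-cell asymmetry values anchored at sister
# centroids, superimposition of all wings into one common frame, 300 x 300
# group grids by linear barycentric interpolation, and blurred
# treatment-minus-control difference maps.

#' Per-cell asymmetry values of one aligned pair
#'
#' For every matched sister-cell pair, computes the mean of the two
#' directional comparisons: for shape traits the absolute trait difference
#' as a percentage of the reference direction's value; for the centroid
#' trait the Euclidean distance between sister centroids (um). Values are
#' anchored at the mean sister-centroid position in the aligned frame.
#'
#' @param pa A `"full"` result of [pair_asymmetry()] (aligned pair plus both
#'   sister maps and feature tables).
#' @param trait One of `"area"`, `"length"`, `"width"`, `"circularity"`
#'   (shape traits, percent) or `"centroid"` (position trait, um).
#' @return A data frame `x`, `y` (um, aligned frame), `value`.
#' @export
per_cell_asymmetry <- function(pa, trait = c("circularity", "area", "length",
                                             "width", "centroid")) {
  trait <- match.arg(trait)
  map <- pa$map_lr$cells
  if (!nrow(map)) return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  fl <- pa$feats_l; fr <- pa$feats_r
  il <- match(map$from, as.character(fl$cell_id))
  ir <- match(map$to, as.character(fr$cell_id))
  anchor_x <- (fl$centroid_x[il] + fr$centroid_x[ir]) / 2
  anchor_y <- (fl$centroid_y[il] + fr$centroid_y[ir]) / 2
  if (trait == "centroid") {
    value <- map$dist
  } else {
    vl <- fl[[trait]][il]; vr <- fr[[trait]][ir]
    # mean of the two directional percent differences
    value <- 100 * (abs(vl - vr) / vl + abs(vl - vr) / vr) / 2
  }
  data.frame(x = anchor_x, y = anchor_y, value = value)
}

#' Superimpose wings into a common spatial frame
#'
#' Each wing is rotated so that the least-squares line through its upper
#' wing edge is horizontal, then translated so its center of gravity sits
#' at the origin. The upper edge is taken as the upper envelope of the
#' outline — the topmost outline point in each of 40 x-bins across the
#' middle 80% of the wing's extent — which keeps the edge point set
#' covariant under rotation (a plain top-y quantile rule would always
#' select the apex of the curved outline and lose the rotation signal).
#'
#' @param wings List of `wing_geometry` objects (right wings should be
#'   mirrored into left orientation beforehand, e.g. via [align_pair()]).
#' @param n_bins Number of x-bins used for the upper envelope.
#' @return A list of transforms, each `list(theta, shift)` such that
#'   `apply_frame_transform(points, tf)` maps aligned-frame points into the
#'   common frame.
#' @export
superimpose_common_frame <- function(wings, n_bins = 40L) {
  upper_slope <- function(o) {
    xr <- range(o[, 1])
    if (diff(xr) < 1e-9) stop("degenerate outline: upper edge undefined")
    lo <- xr[1] + 0.1 * diff(xr); hi <- xr[2] - 0.1 * diff(xr)
    mid <- o[, 1] >= lo & o[, 1] <= hi
    if (sum(mid) < 3) stop("degenerate outline: upper edge undefined")
    ot <- o[mid, , drop = FALSE]
    bin <- pmin(n_bins, 1L + floor((ot[, 1] - lo) / (hi - lo) * n_bins))
    top <- vapply(split(seq_len(nrow(ot)), bin), function(ix)
      ix[which.max(ot[ix, 2])], integer(1))
    upper <- ot[top, , drop = FALSE]
    if (nrow(upper) < 2 || diff(range(upper[, 1])) < 1e-9)
      stop("degenerate outline: upper edge undefined")
    coef(lm(upper[, 2] ~ upper[, 1]))[[2]]
  }
  lapply(wings, function(w) {
    o <- resample_closed(w$outline, max(400L, nrow(w$outline)))
    # iterate the edge fit to its fixed point: every pose of the same wing
    # then converges to one canonical orientation
    theta <- 0
    for (it in 1:25) {
      step <- -atan(upper_slope(rotate_points(o, theta)))
      theta <- theta + step
      if (abs(step) < 1e-7) break
    }
    rot_outline <- rotate_points(o, theta)
    shift <- -poly_centroid(rot_outline)
    list(theta = theta, shift = shift)
  })
}

#' Apply a common-frame transform to points
#'
#' @param points n x 2 matrix or data frame with `x`, `y`.
#' @param tf A transform from [superimpose_common_frame()].
#' @return Transformed points in the same container type.
#' @export
apply_frame_transform <- function(points, tf) {
  df <- is.data.frame(points)
  m <- if (df) cbind(points$x, points$y) else points
  m <- sweep(rotate_points(m, tf$theta), 2, -tf$shift)
  if (df) {
    points$x <- m[, 1]; points$y <- m[, 2]
    points
  } else m
}

#' Group-level asymmetry grid (300 x 300)
#'
#' Interpolates each wing's scattered per-cell asymmetry values onto a
#' common 300 x 300 grid (linear barycentric interpolation over the wing's
#' convex hull) and averages over wings pointwise, ignoring missing nodes.
#' With `trim = TRUE` (used for circularity and width) values below the 5th
#' and above the 95th percentile, pooled within the group, are dropped
#' before gridding.
#'
#' @param points_list List (one entry per wing) of data frames `x`, `y`,
#'   `value` in the common frame.
#' @param trait,group Labels stored on the grid.
#' @param trim Apply the pooled 5%/95% trim before gridding.
#' @param grid_n Grid resolution per axis.
#' @param extent Optional list `xlim`, `ylim`; defaults to the pooled
#'   bounding box padded by 2%.
#' @param trim_quantiles Lower/upper trim quantiles.
#' @return An object of class `asymmetry_grid`: `values` (grid_n x grid_n
#'   matrix, `NA` = missing), `xlim`, `ylim`, `trait`, `group`, `n_wings`.
#' @export
build_group_grid <- function(points_list, trait = "", group = "",
                             trim = FALSE, grid_n = 300L, extent = NULL,
                             trim_quantiles = c(0.05, 0.95)) {
  points_list <- points_list[vapply(points_list, nrow, integer(1)) > 0]
  all_pts <- do.call(rbind, points_list)
  if (is.null(all_pts) || nrow(all_pts) < 3)
    stop("need at least 3 points to build a grid")
  if (trim) {
    qs <- quantile(all_pts$value, trim_quantiles, names = FALSE)
    points_list <- lapply(points_list, function(p)
      p[p$value >= qs[1] & p$value <= qs[2], , drop = FALSE])
    points_list <- points_list[vapply(points_list, nrow, integer(1)) >= 3]
    all_pts <- do.call(rbind, points_list)
    if (is.null(all_pts) || nrow(all_pts) < 3)
      stop("trim removed too many points")
  }
  if (is.null(extent)) {
    pad <- 0.02
    xr <- range(all_pts$x); yr <- range(all_pts$y)
    extent <- list(xlim = xr + c(-1, 1) * pad * diff(xr),
                   ylim = yr + c(-1, 1) * pad * diff(yr))
  }
  gx <- seq(extent$xlim[1], extent$xlim[2], length.out = grid_n)
  gy <- seq(extent$ylim[1], extent$ylim[2], length.out = grid_n)

  acc <- matrix(0, grid_n, grid_n)
  cnt <- matrix(0L, grid_n, grid_n)
  used <- 0L
  for (p in points_list) {
    if (nrow(p) < 3 || diff(range(p$x)) < 1e-12 || diff(range(p$y)) < 1e-12) next
    z <- tryCatch(
      interp::interp(x = p$x, y = p$y, z = p$value, xo = gx, yo = gy,
                     method = "linear", duplicate = "mean")$z,
      error = function(e) NULL)
    if (is.null(z)) next
    ok <- is.finite(z)
    acc[ok] <- acc[ok] + z[ok]
    cnt[ok] <- cnt[ok] + 1L
    used <- used + 1L
  }
  if (used == 0L) stop("no wing yielded an interpolable point set (collinear points?)")
  vals <- acc / cnt
  vals[cnt == 0L] <- NA_real_
  # interp returns z[x, y]; store as [row = y (bottom-up), col = x]
  structure(list(values = t(vals), x = gx, y = gy,
                 xlim = extent$xlim, ylim = extent$ylim,
                 trait = trait, group = group, n_wings = used),
            class = "asymmetry_grid")
}

#' Treatment-minus-control difference map with Gaussian blur
#'
#' Subtracts two group grids elementwise on co-valid nodes and applies a
#' missing-value-aware Gaussian blur (blur of values divided by blur of the
#' validity mask), so that missing regions outside the wing do not pull the
#' map toward zero. Positive values mean higher asymmetry under treatment.
#'
#' @param grid_treatment,grid_control `asymmetry_grid`s on identical
#'   extents.
#' @param blur_sigma Gaussian sigma in grid-cell units (default 10).
#' @return An `asymmetry_grid` holding the blurred difference.
#' @export
difference_map <- function(grid_treatment, grid_control, blur_sigma = 10) {
  gt <- grid_treatment; gc_ <- grid_control
  if (!isTRUE(all.equal(gt$xlim, gc_$xlim)) ||
      !isTRUE(all.equal(gt$ylim, gc_$ylim)) ||
      !all(dim(gt$values) == dim(gc_$values)))
    stop("grid extents do not match")
  d <- gt$values - gc_$values
  if (blur_sigma > 0) d <- gaussian_blur_na(d, blur_sigma)
  structure(list(values = d, x = gt$x, y = gt$y,
                 xlim = gt$xlim, ylim = gt$ylim,
                 trait = gt$trait,
                 group = paste0(gt$group, " - ", gc_$group),
                 n_wings = min(gt$n_wings, gc_$n_wings)),
            class = "asymmetry_grid")
}

#' Missing-value-aware Gaussian blur
#'
#' Separable Gaussian convolution with mask normalization: the blur of the
#' zero-filled values is divided by the blur of the validity mask. Nodes
#' with no valid support stay `NA`.
#'
#' @param mat Numeric matrix, `NA` = missing.
#' @param sigma Gaussian sigma in cell units.
#' @return Blurred matrix of the same dimension.
#' @export
gaussian_blur_na <- function(mat, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  valid <- is.finite(mat)
  v0 <- mat; v0[!valid] <- 0
  conv1 <- function(m) {
    # convolve each column with k, zero-padded edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      w <- k[o + r + 1]
      src <- seq_len(n) + o
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + w * m[src[ok], ]
    }
    out
  }
  num <- t(conv1(t(conv1(v0))))
  den <- t(conv1(t(conv1(valid * 1))))
  out <- num / den
  # stay on the original support: smoothing must not extrapolate beyond it
  out[!valid | den < 1e-12] <- NA_real_
  out
}

#' @export
print.asymmetry_grid <- function(x, ...) {
  cat(sprintf("<asymmetry_grid> %s | %s: %dx%d nodes, %d wings, %.1f%% valid\n",
              x$trait, x$group, nrow(x$values), ncol(x$values), x$n_wings,
              100 * mean(is.finite(x$values))))
  invisible(x)
}

#' Plot an asymmetry grid as a heatmap
#'
#' Sequential palette for group grids, diverging palette (blue-white-red,
#' red = asymmetry increase) for difference maps.
#'
#' @param x An `asymmetry_grid`.
#' @param diverging Use a symmetric diverging palette centered at zero.
#' @param ... Passed to [graphics::image()].
#' @export
plot.asymmetry_grid <- function(x, diverging = grepl(" - ", x$group), ...) {
  v <- t(x$values)  # image() wants [x, y]
  if (diverging) {
    m <- max(abs(v), na.rm = TRUE)
    breaks <- seq(-m, m, length.out = 65)
    col <- colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
    image(x$x, x$y, v, breaks = breaks, col = col, asp = 1,
          xlab = "x (um)", ylab = "y (um)",
          main = paste(x$trait, x$group, sep = " | "), ...)
  } else {
    col <- colorRampPalette(c("black", "#6a1f99", "#f7e14b"))(64)
    image(x$x, x$y, v, col = col, asp = 1,
          xlab = "x (um)", ylab = "y (um)",
          main = paste(x$trait, x$group, sep = " | "), ...)
  }
  invisible(x)
}
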