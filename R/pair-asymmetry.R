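# Mirror alignment, optimal sister matching, and the pairwise asymmetry
# variable inventory (NRMSE of cell traits, mean distances, subtract values,
# wing size differences). All asymmetry variables average the two comparison
# directions (left/right and right/left).

#' Mirror and align a left/right wing pair
#'
#' The right wing is reflected across the vertical axis, both wings are
#' translated to their outline centroid, and the right wing is rotated to
#' minimize the symmetric mean nearest-point distance between the two
#' outlines (coarse angular scan refined by golden-section search to 1e-4
#' rad). No scaling is applied: size asymmetry is part of the signal.
#'
#' @param left,right `wing_geometry` objects (the right wing in its native,
#'   mirrored orientation).
#' @param n_outline_points Number of arc-length-uniform outline points used
#'   by the alignment objective.
#' @param max_angle Half-width (rad) of the coarse rotation scan.
#' @param n_coarse Number of coarse-scan angles.
#' @param reflect_right Set `FALSE` if the right wing is already reflected
#'   into left orientation.
#' @return A list of class `aligned_pair`: `left`, `right` (both in the
#'   aligned frame), `angle` (rad, applied to the right wing),
#'   `outline_distance` (um, post-alignment symmetric mean nearest-point
#'   distance).
#' @examples
#' pair <- generate_wing_pair(synthetic_config(cells_target = 40), 1)
#' al <- align_pair(pair$left, pair$right)
#' al$outline_distance
#' @export
align_pair <- function(left, right, n_outline_points = 200L,
                       max_angle = pi / 4, n_coarse = 41L,
                       reflect_right = TRUE) {
  if (reflect_right) right <- mirror_geometry(right)
  left <- translate_geometry(left, -poly_centroid(left$outline))
  right <- translate_geometry(right, -poly_centroid(right$outline))

  a_rs <- resample_closed(left$outline, n_outline_points)
  b_rs <- resample_closed(right$outline, n_outline_points)
  obj <- function(th) sym_outline_dist(a_rs, rotate_points(b_rs, th))

  # coarse scan, batched over all candidate angles
  coarse <- seq(-max_angle, max_angle, length.out = n_coarse)
  m <- nrow(b_rs)
  BX <- outer(b_rs[, 1], cos(coarse)) - outer(b_rs[, 2], sin(coarse))
  BY <- outer(b_rs[, 1], sin(coarse)) + outer(b_rs[, 2], cos(coarse))
  P <- cbind(as.vector(BX), as.vector(BY))
  d2 <- pdist2(P, a_rs)
  nb <- max.col(-d2, ties.method = "first")
  d_b2a <- sqrt(rowSums((P - a_rs[nb, , drop = FALSE])^2))
  mean_b2a <- colMeans(matrix(d_b2a, m, n_coarse))
  mean_a2b <- numeric(n_coarse)
  for (k in seq_len(n_coarse)) {
    rows <- ((k - 1) * m + 1):(k * m)
    ia <- max.col(-t(d2[rows, , drop = FALSE]), ties.method = "first")
    Pk <- P[rows, , drop = FALSE]
    mean_a2b[k] <- mean(sqrt(rowSums((a_rs - Pk[ia, , drop = FALSE])^2)))
  }
  fc <- (mean_b2a + mean_a2b) / 2
  if (!all(is.finite(fc)))
    stop("alignment failed: non-finite outline distance (degenerate outline?)")
  k <- which.min(fc)
  lo <- coarse[max(1L, k - 1L)]; hi <- coarse[min(length(coarse), k + 1L)]
  opt <- optimize(obj, c(lo, hi), tol = 1e-4)
  # snap to the best of {0, coarse best, refined}: keeps the noise-free
  # mirror identity exact instead of within search tolerance
  cand <- c(0, coarse[k], opt$minimum)
  fv <- c(obj(0), fc[k], opt$objective)
  angle <- cand[which.min(fv)]

  right <- rotate_geometry(right, angle)
  structure(list(left = left, right = right, angle = angle,
                 outline_distance = min(fv)),
            class = "aligned_pair")
}

rotate_geometry <- function(g, theta) {
  if (theta == 0) return(g)
  g$outline <- rotate_points(g$outline, theta)
  g$cells <- lapply(g$cells, function(cl) {
    cl$vertices <- rotate_points(cl$vertices, theta); cl
  })
  xy <- rotate_points(cbind(g$junctions$x, g$junctions$y), theta)
  g$junctions$x <- xy[, 1]; g$junctions$y <- xy[, 2]
  if (!is.null(g$landmarks)) g$landmarks <- rotate_points(g$landmarks, theta)
  g
}

#' Match sister cells and junctions between aligned wings
#'
#' Optimal one-to-one assignment (Hungarian algorithm) minimizing total
#' centroid distance, gated: pairs farther apart than `gate_frac` of the
#' wing length stay unmatched. Junctions are matched the same way.
#'
#' @param aligned An `aligned_pair` from [align_pair()].
#' @param direction `"LR"` (left is the reference side) or `"RL"`.
#' @param gate_frac Gate distance as a fraction of wing length.
#' @return A list of class `sister_map`: `direction`, `cells` and
#'   `junctions` (data frames `from`, `to`, `dist` in um, ids of the
#'   respective geometries), `unmatched_from`, `unmatched_to` (cell ids).
#' @export
match_sisters <- function(aligned, direction = c("LR", "RL"), gate_frac = 0.25) {
  direction <- match.arg(direction)
  src <- if (direction == "LR") aligned$left else aligned$right
  dst <- if (direction == "LR") aligned$right else aligned$left
  gate <- gate_frac * principal_extents(aligned$left$outline)[["length"]]

  cm_src <- cell_centroid_matrix(src)
  cm_dst <- cell_centroid_matrix(dst)
  cells <- gated_assignment(cm_src, cm_dst, gate)

  jm_src <- cbind(src$junctions$x, src$junctions$y)
  jm_dst <- cbind(dst$junctions$x, dst$junctions$y)
  rownames(jm_src) <- src$junctions$id
  rownames(jm_dst) <- dst$junctions$id
  junct <- gated_assignment(jm_src, jm_dst, gate)

  structure(list(direction = direction, cells = cells$matched,
                 junctions = junct$matched,
                 unmatched_from = cells$unmatched_from,
                 unmatched_to = cells$unmatched_to),
            class = "sister_map")
}

cell_centroid_matrix <- function(g) {
  if (!length(g$cells))
    return(matrix(numeric(0), 0, 2, dimnames = list(character(0), NULL)))
  m <- t(vapply(g$cells, function(cl) poly_centroid(cl$vertices), numeric(2)))
  rownames(m) <- vapply(g$cells, function(cl) as.character(cl$id), character(1))
  m
}

# Hungarian assignment from rows of a to rows of b with a distance gate.
# The gate enters the optimization itself: the cost matrix is padded with
# per-point dummy partners at the gate cost, so the solver can leave points
# unmatched instead of absorbing them through long cascade matches (the
# classical failure mode when the two point sets differ in membership).
gated_assignment <- function(a, b, gate) {
  ids_a <- rownames(a); ids_b <- rownames(b)
  na <- nrow(a); nb <- nrow(b)
  empty <- data.frame(from = character(0), to = character(0), dist = numeric(0))
  if (na == 0 || nb == 0) {
    return(list(matched = empty, unmatched_from = ids_a, unmatched_to = ids_b))
  }
  d <- sqrt(pdist2(a, b))
  big <- (max(d) + gate) * (na + nb)
  n <- na + nb
  cost <- matrix(0, n, n)
  cost[seq_len(na), seq_len(nb)] <- d
  cost[seq_len(na), nb + seq_len(na)] <- big
  cost[na + seq_len(nb), seq_len(nb)] <- big
  cost[cbind(seq_len(na), nb + seq_len(na))] <- gate
  cost[cbind(na + seq_len(nb), seq_len(nb))] <- gate
  sol <- as.integer(clue::solve_LSAP(cost))
  from <- seq_len(na)
  to <- sol[seq_len(na)]
  keep <- to <= nb
  from <- from[keep]; to <- to[keep]
  dd <- sqrt(rowSums((a[from, , drop = FALSE] - b[to, , drop = FALSE])^2))
  ok <- dd <= gate
  matched <- data.frame(from = ids_a[from[ok]], to = ids_b[to[ok]],
                        dist = dd[ok], stringsAsFactors = FALSE)
  list(matched = matched,
       unmatched_from = setdiff(ids_a, matched$from),
       unmatched_to = setdiff(ids_b, matched$to))
}

#' Normalized root mean square error between matched trait values
#'
#' `sqrt(mean((ref - other)^2)) / mean(ref)`. The package reports the mean
#' of the two comparison directions wherever NRMSE enters the asymmetry
#' record.
#'
#' @param values_ref Trait values of the reference side (matched order).
#' @param values_other Corresponding values of the other side.
#' @return Dimensionless NRMSE; `NA` with a warning for an empty match set.
#' @examples
#' nrmse(c(1, 2), c(2, 1))  # 1 / 1.5
#' @export
nrmse <- function(values_ref, values_other) {
  stopifnot(length(values_ref) == length(values_other))
  if (!length(values_ref)) {
    warning("empty match set: NRMSE undefined")
    return(NA_real_)
  }
  m <- mean(values_ref)
  stopifnot(m > 0)
  sqrt(mean((values_ref - values_other)^2)) / m
}

# Bidirectional NRMSE of one cell trait given both sister maps.
nrmse_bidirectional <- function(map_lr, map_rl, feats_l, feats_r, trait) {
  v <- function(map, ref_is_left) {
    fl <- feats_l[[trait]][match(map$cells$from, as.character(feats_l$cell_id))]
    fr <- feats_r[[trait]][match(map$cells$to, as.character(feats_r$cell_id))]
    if (ref_is_left) nrmse(fl, fr) else nrmse(fr, fl)
  }
  lr <- v(map_lr, TRUE)
  # RL map: from = right ids, to = left ids
  frr <- feats_r[[trait]][match(map_rl$cells$from, as.character(feats_r$cell_id))]
  fll <- feats_l[[trait]][match(map_rl$cells$to, as.character(feats_l$cell_id))]
  rl <- nrmse(frr, fll)
  mean(c(lr, rl))
}

#' Full asymmetry record of one wing pair
#'
#' Computes the complete pairwise variable inventory: bidirectional NRMSE of
#' cell area, length, width and circularity; mean distances between matched
#' junctions, matched cell centroids, and the two outlines; subtract values
#' (absolute count differences) for cells and junctions; wing size means and
#' absolute differences.
#'
#' @param aligned An `aligned_pair`.
#' @param map_lr,map_rl `sister_map`s for both directions.
#' @param feats_l,feats_r Optional precomputed [cell_features_table()]s.
#' @param n_outline_points Outline resampling used for the outline distance.
#' @return A one-row data frame; sizes in mm/mm^2, distances in um, NRMSE
#'   dimensionless, counts as means of the two sides.
#' @export
asymmetry_record <- function(aligned, map_lr, map_rl,
                             feats_l = NULL, feats_r = NULL,
                             n_outline_points = 500L) {
  if (is.null(feats_l)) feats_l <- cell_features_table(aligned$left)
  if (is.null(feats_r)) feats_r <- cell_features_table(aligned$right)

  wf_l <- wing_features(aligned$left)
  wf_r <- wing_features(aligned$right)

  mdj <- mean(c(mean(map_lr$junctions$dist), mean(map_rl$junctions$dist)))
  mdc <- mean(c(mean(map_lr$cells$dist), mean(map_rl$cells$dist)))
  a_rs <- resample_closed(aligned$left$outline, n_outline_points)
  b_rs <- resample_closed(aligned$right$outline, n_outline_points)

  data.frame(
    nrmse_area = nrmse_bidirectional(map_lr, map_rl, feats_l, feats_r, "area"),
    nrmse_length = nrmse_bidirectional(map_lr, map_rl, feats_l, feats_r, "length"),
    nrmse_width = nrmse_bidirectional(map_lr, map_rl, feats_l, feats_r, "width"),
    nrmse_circularity = nrmse_bidirectional(map_lr, map_rl, feats_l, feats_r, "circularity"),
    mean_dist_junctions = mdj,
    mean_dist_centroids = mdc,
    mean_dist_outlines = sym_outline_dist(a_rs, b_rs),
    subtract_cells = abs(wf_l$n_cells - wf_r$n_cells),
    subtract_junctions = abs(wf_l$n_junctions - wf_r$n_junctions),
    wing_area_diff = abs(wf_l$area - wf_r$area) / 1e6,
    wing_perimeter_diff = abs(wf_l$perimeter - wf_r$perimeter) / 1e3,
    wing_area = (wf_l$area + wf_r$area) / 2 / 1e6,
    wing_perimeter = (wf_l$perimeter + wf_r$perimeter) / 2 / 1e3,
    wing_length = (wf_l$length + wf_r$length) / 2 / 1e3,
    wing_width = (wf_l$width + wf_r$width) / 2 / 1e3,
    n_cells = (wf_l$n_cells + wf_r$n_cells) / 2,
    n_junctions = (wf_l$n_junctions + wf_r$n_junctions) / 2
  )
}

#' Align, match and score one wing pair in a single call
#'
#' @param left,right `wing_geometry` objects.
#' @param gate_frac Matching gate as a fraction of wing length.
#' @param n_outline_points Outline resampling for alignment and the outline
#'   distance.
#' @param outline_distance_points Arc-length-uniform resampling used for the
#'   record's outline-distance variable (default 500).
#' @param max_angle,n_coarse Rotation search range and coarse-scan size
#'   passed to [align_pair()].
#' @param keep `"record"` returns the one-row record; `"full"` additionally
#'   returns the aligned pair and both sister maps.
#' @return A one-row data frame (see [asymmetry_record()]), or a list with
#'   `record`, `aligned`, `map_lr`, `map_rl`, `feats_l`, `feats_r`.
#' @examples
#' pair <- generate_wing_pair(synthetic_config(cells_target = 40), 1)
#' pair_asymmetry(pair$left, pair$right)
#' @export
pair_asymmetry <- function(left, right, gate_frac = 0.25,
                           n_outline_points = 200L,
                           outline_distance_points = 500L,
                           max_angle = pi / 4, n_coarse = 41L,
                           keep = c("record", "full")) {
  keep <- match.arg(keep)
  al <- align_pair(left, right, n_outline_points = n_outline_points,
                   max_angle = max_angle, n_coarse = n_coarse)
  map_lr <- match_sisters(al, "LR", gate_frac)
  map_rl <- match_sisters(al, "RL", gate_frac)
  fl <- cell_features_table(al$left)
  fr <- cell_features_table(al$right)
  rec <- asymmetry_record(al, map_lr, map_rl, fl, fr,
                          n_outline_points = outline_distance_points)
  if (keep == "record") return(rec)
  list(record = rec, aligned = al, map_lr = map_lr, map_rl = map_rl,
       feats_l = fl, feats_r = fr)
}

#' Screen a signed left-minus-right trait for DA and antisymmetry
#'
#' Valid fluctuating-asymmetry interpretation requires signed L-R
#' differences with zero mean (no directional asymmetry) and a normal,
#' unimodal distribution (no antisymmetry). The screen combines a one-sample
#' t-test of zero mean with a D'Agostino-type normality test; antisymmetry
#' is flagged when normality is rejected together with a platykurtic
#' (negative kurtosis z) signature, the classical bimodality fingerprint of
#' antisymmetric mixtures.
#'
#' @param signed_differences Per-individual signed L-R values (n >= 3; the
#'   kurtosis component requires n >= 20).
#' @param alpha Significance level for the flags.
#' @return A list: `p_mean_zero`, `p_normality` (K2 omnibus), `z_skewness`,
#'   `z_kurtosis`, `excess_kurtosis`, `directional_asymmetry` flag,
#'   `antisymmetry` flag, `n`.
#' @examples
#' screen_symmetry_type(rnorm(50))
#' @export
screen_symmetry_type <- function(signed_differences, alpha = 0.05) {
  d <- signed_differences[is.finite(signed_differences)]
  n <- length(d)
  if (n < 3) stop("need at least 3 signed differences")
  p_mean <- t.test(d)$p.value
  k2 <- dagostino_k2(d)
  list(p_mean_zero = p_mean,
       p_normality = k2$p_k2,
       z_skewness = k2$z_skew,
       z_kurtosis = k2$z_kurt,
       excess_kurtosis = k2$excess_kurtosis,
       directional_asymmetry = p_mean < alpha,
       antisymmetry = is.finite(k2$p_k2) && k2$p_k2 < alpha &&
         is.finite(k2$excess_kurtosis) && k2$excess_kurtosis < 0,
       n = n)
}

#' D'Agostino normality test (skewness, kurtosis and K2 omnibus)
#'
#' Moment-based normality test: transformed sample skewness z, transformed
#' sample kurtosis z (Anscombe-Glynn), and the K2 = z1^2 + z2^2 omnibus
#' statistic referred to chi-square with 2 df.
#'
#' @param x Numeric sample (skewness z needs n >= 8, kurtosis z n >= 20).
#' @return A list: `z_skew`, `p_skew`, `z_kurt`, `p_kurt`,
#'   `excess_kurtosis` (raw direction, sign-safe in the extreme regime),
#'   `k2`, `p_k2`.
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  out <- list(z_skew = NA_real_, p_skew = NA_real_,
              z_kurt = NA_real_, p_kurt = NA_real_,
              excess_kurtosis = NA_real_,
              k2 = NA_real_, p_k2 = NA_real_)
  if (m2 <= 0) return(out)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # raw direction of the kurtosis deviation; the Anscombe-Glynn z loses its
  # sign in the extreme platykurtic regime (cube root of a negative ratio)
  out$excess_kurtosis <- b2 - 3 * (n - 1) / (n + 1)

  if (n >= 8) {
    y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
      ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    w2 <- -1 + sqrt(2 * (beta2 - 1))
    delta <- 1 / sqrt(log(sqrt(w2)))
    alpha <- sqrt(2 / (w2 - 1))
    out$z_skew <- delta * asinh(y / alpha)
    out$p_skew <- 2 * pnorm(-abs(out$z_skew))
  }
  if (n >= 20) {
    eb2 <- 3 * (n - 1) / (n + 1)
    vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    xx <- (b2 - eb2) / sqrt(vb2)
    sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
      sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
    num <- 1 - 2 / a
    den <- 1 + xx * sqrt(2 / (a - 4))
    ratio <- num / den
    out$z_kurt <- ((1 - 2 / (9 * a)) - sign(ratio) * abs(ratio)^(1 / 3)) /
      sqrt(2 / (9 * a))
    out$p_kurt <- 2 * pnorm(-abs(out$z_kurt))
  }
  if (is.finite(out$z_skew) && is.finite(out$z_kurt)) {
    out$k2 <- out$z_skew^2 + out$z_kurt^2
    out$p_k2 <- pchisq(out$k2, df = 2, lower.tail = FALSE)
  }
  out
}
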