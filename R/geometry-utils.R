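# Low-level planar geometry helpers. All polygons are n x 2 matrices of
# vertices in order (open rings: last vertex != first); coordinates in um.

#' Polygon area (shoelace formula)
#'
#' @param xy n x 2 matrix of polygon vertices in order (not closed).
#' @return Absolute enclosed area.
#' @keywords internal
poly_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

poly_signed_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]) / 2
}

poly_perimeter <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  sum(sqrt(rowSums((xy[i2, , drop = FALSE] - xy)^2)))
}

# Area-weighted centroid of a simple polygon; falls back to the vertex mean
# for (near-)degenerate rings.
poly_centroid <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  cr <- xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  cx <- sum((xy[, 1] + xy[i2, 1]) * cr) / (6 * a)
  cy <- sum((xy[, 2] + xy[i2, 2]) * cr) / (6 * a)
  c(cx, cy)
}

# Extents of the vertex cloud along the principal axes of its covariance
# (closed-form 2x2 eigen direction). Returns c(length, width), length >= width.
principal_extents <- function(xy) {
  n <- nrow(xy)
  mx <- sum(xy[, 1]) / n; my <- sum(xy[, 2]) / n
  dx <- xy[, 1] - mx; dy <- xy[, 2] - my
  a <- sum(dx * dx); b <- sum(dx * dy); cc <- sum(dy * dy)
  th <- 0.5 * atan2(2 * b, a - cc)
  cs <- cos(th); sn <- sin(th)
  p1 <- dx * cs + dy * sn
  p2 <- -dx * sn + dy * cs
  e1 <- max(p1) - min(p1); e2 <- max(p2) - min(p2)
  c(length = max(e1, e2), width = min(e1, e2))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

rotate_points <- function(xy, theta) xy %*% t(rot2(theta))

reflect_x <- function(xy) {
  xy[, 1] <- -xy[, 1]
  xy
}

# Arc-length-uniform resampling of a closed polygon to n points.
resample_closed <- function(xy, n) {
  m <- nrow(xy)
  ring <- rbind(xy, xy[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(ring)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1]
  s <- seq(0, total, length.out = n + 1)[-(n + 1)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-300)
  ring[idx, , drop = FALSE] + frac * (ring[idx + 1, , drop = FALSE] - ring[idx, , drop = FALSE])
}

# Squared cross-distance matrix between two point sets (na x nb).
pdist2 <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Mean over points of a of the distance to the nearest point of b. The
# cross-distance matrix selects the neighbour; the reported distance is
# recomputed from coordinate differences (exact for coincident points).
mean_nn_dist <- function(a, b) {
  idx <- max.col(-pdist2(a, b), ties.method = "first")
  mean(sqrt(rowSums((a - b[idx, , drop = FALSE])^2)))
}

# Symmetric mean nearest-point distance between two outlines (one distance
# matrix, both directions).
sym_outline_dist <- function(a, b) {
  d2 <- pdist2(a, b)
  ia <- max.col(-d2, ties.method = "first")
  ib <- max.col(-t(d2), ties.method = "first")
  (mean(sqrt(rowSums((a - b[ia, , drop = FALSE])^2))) +
      mean(sqrt(rowSums((b - a[ib, , drop = FALSE])^2)))) / 2
}

# Vectorized point-in-convex-polygon test (poly in CCW order).
points_in_convex <- function(pts, poly, tol = 0) {
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  ex <- poly[i2, 1] - poly[, 1]
  ey <- poly[i2, 2] - poly[, 2]
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(n)) {
    cr <- ex[k] * (pts[, 2] - poly[k, 2]) - ey[k] * (pts[, 1] - poly[k, 1])
    inside <- inside & (cr > tol)
    if (!any(inside)) break
  }
  inside
}

is_convex_poly <- function(xy) {
  n <- nrow(xy)
  e1 <- xy[c(2:n, 1), , drop = FALSE] - xy
  e2 <- xy[c(3:n, 1:2), , drop = FALSE] - xy[c(2:n, 1), , drop = FALSE]
  cr <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  all(cr > 0) || all(cr < 0)
}

# Sutherland-Hodgman clipping of a subject polygon against a convex clip
# polygon (CCW). Clip edges whose half-plane contains the whole subject
# bounding box are skipped up front; the per-edge clipping step is
# vectorized over subject vertices. Returns a matrix (possibly 0 rows).
convex_clip <- function(subject, clip) {
  if (poly_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  n <- nrow(clip)
  i2 <- c(2:n, 1)
  ex <- clip[i2, 1] - clip[, 1]
  ey <- clip[i2, 2] - clip[, 2]
  bx <- range(subject[, 1]); by <- range(subject[, 2])
  cx <- c(bx[1], bx[2], bx[1], bx[2]); cy <- c(by[1], by[1], by[2], by[2])
  # signed position of the 4 bbox corners wrt every clip edge
  crn <- outer(ex, cy) - outer(ey, cx) + (ey * clip[, 1] - ex * clip[, 2])
  active <- which(pmin(crn[, 1], crn[, 2], crn[, 3], crn[, 4]) < 0)
  out <- subject
  for (k in active) {
    m <- nrow(out)
    if (m == 0) break
    sgn <- ex[k] * (out[, 2] - clip[k, 2]) - ey[k] * (out[, 1] - clip[k, 1])
    if (all(sgn >= 0)) next
    j2 <- c(2:m, 1)
    cur <- sgn >= 0
    nxt <- cur[j2]
    crs <- cur != nxt
    t_ <- sgn / (sgn - sgn[j2])
    ip <- out + t_ * (out[j2, , drop = FALSE] - out)
    M <- matrix(NA_real_, 2 * m, 2)
    odd <- seq(1, 2 * m, 2)
    M[odd, ] <- out
    M[odd + 1, ] <- ip
    sel <- logical(2 * m)
    sel[odd] <- cur
    sel[odd + 1] <- crs
    out <- M[sel, , drop = FALSE]
  }
  out
}

# Deduplicate consecutive (nearly) identical vertices.
dedup_poly <- function(xy, tol = 1e-9) {
  if (nrow(xy) < 2) return(xy)
  n <- nrow(xy)
  d <- sqrt(rowSums((xy - xy[c(n, 1:(n - 1)), , drop = FALSE])^2))
  xy[d > tol, , drop = FALSE]
}
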