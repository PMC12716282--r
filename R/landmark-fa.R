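# Landmark-based shape analysis: generalized Procrustes alignment and the
# bilateral (matching) symmetry decomposition into directional asymmetry and
# per-individual fluctuating-asymmetry scores.

#' Generalized Procrustes alignment of landmark configurations
#'
#' Translates every configuration to its centroid, scales to unit centroid
#' size, and iteratively rotates all configurations to their consensus until
#' the consensus change falls below `tol` (full ordinary Procrustes
#' rotations via SVD; reflections are not part of the fitted transform —
#' right-side configurations are reflected explicitly beforehand).
#'
#' @param shapes A k x 2 x n array, or a list of k x 2 matrices.
#' @param reflect Logical vector of length n (or scalar): configurations to
#'   reflect across the vertical axis before fitting (i.e. right wings when
#'   fitting both sides of paired organs).
#' @param tol Convergence tolerance on the consensus root-mean-square
#'   change.
#' @param max_iter Maximum number of alignment sweeps.
#' @return A list of class `gpa_fit`: `aligned` (k x 2 x n array),
#'   `consensus` (k x 2, unit centroid size), `iterations`, `converged`.
#' @examples
#' tri <- matrix(c(0, 0, 1, 0, 0.4, 0.9), 3, 2, byrow = TRUE)
#' shapes <- list(tri, tri * 2, rotate_shape(tri, 0.5))
#' fit <- gpa(shapes)
#' @export
gpa <- function(shapes, reflect = FALSE, tol = 1e-10, max_iter = 100L) {
  arr <- as_shape_array(shapes)
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 1) stop("need at least one configuration")
  reflect <- rep_len(reflect, n)

  for (i in seq_len(n)) {
    s <- arr[, , i]
    if (reflect[i]) s[, 1] <- -s[, 1]
    s <- sweep(s, 2, colMeans(s))
    cs <- sqrt(sum(s^2))
    if (cs < 1e-12) stop("degenerate configuration (zero centroid size)")
    if (qr(s)$rank < 2) stop("rank-deficient configuration (collinear landmarks)")
    arr[, , i] <- s / cs
  }
  if (n == 1) {
    return(structure(list(aligned = arr, consensus = arr[, , 1],
                          iterations = 0L, converged = TRUE),
                     class = "gpa_fit"))
  }

  consensus <- arr[, , 1]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) {
      arr[, , i] <- procrustes_rotate(arr[, , i], consensus)
    }
    new_cons <- apply(arr, c(1, 2), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(aligned = arr, consensus = consensus, iterations = it,
                 converged = converged), class = "gpa_fit")
}

# Optimal rotation of x onto target (both centered, any scale): SVD solution
# restricted to proper rotations.
procrustes_rotate <- function(x, target) {
  s <- svd(crossprod(target, x))
  r <- s$v %*% t(s$u)
  if (det(r) < 0) {
    s$v[, 2] <- -s$v[, 2]
    r <- s$v %*% t(s$u)
  }
  x %*% r
}

as_shape_array <- function(shapes) {
  if (is.array(shapes) && length(dim(shapes)) == 3) return(shapes)
  stopifnot(is.list(shapes), length(shapes) >= 1)
  k <- nrow(shapes[[1]])
  arr <- array(NA_real_, c(k, 2, length(shapes)))
  for (i in seq_along(shapes)) arr[, , i] <- shapes[[i]]
  arr
}

#' Rotate a landmark configuration (utility)
#'
#' @param shape k x 2 matrix.
#' @param theta Rotation angle in radians.
#' @return The rotated k x 2 matrix.
#' @export
rotate_shape <- function(shape, theta) rotate_points(shape, theta)

#' Bilateral-symmetry FA decomposition of aligned wing shapes
#'
#' For each individual with both sides aligned in one Procrustes fit, the
#' asymmetry vector is `a_i = aligned(L)_i - aligned(R)_i` (right side
#' reflected before fitting). Its mean over individuals is the directional
#' asymmetry (DA) component; the individual FA component is `a_i - DA`, and
#' the FA score is its Euclidean norm in shape space — the Procrustes
#' distance of the individual's asymmetry from the mean symmetric shape.
#'
#' @param aligned A `gpa_fit`, or a k x 2 x n array of aligned shapes.
#' @param individual Factor/vector of individual ids, length n.
#' @param side Character vector (`"left"`/`"right"`), length n.
#' @return A list of class `fa_result`: `scores` (data frame `individual`,
#'   `fa_score`), `da` (k x 2 directional-asymmetry component),
#'   `consensus_symmetric` (k x 2 mean symmetric shape, unit centroid
#'   size), `asymmetry` (k x 2 x n_ind individual asymmetry vectors).
#'   Individuals missing a side are dropped with a warning.
#' @export
fa_decomposition <- function(aligned, individual, side) {
  arr <- if (inherits(aligned, "gpa_fit")) aligned$aligned else aligned
  n <- dim(arr)[3]
  stopifnot(length(individual) == n, length(side) == n)
  side <- tolower(as.character(side))
  stopifnot(all(side %in% c("left", "right")))

  ids <- unique(individual)
  keep <- vapply(ids, function(id) {
    sum(individual == id & side == "left") == 1 &&
      sum(individual == id & side == "right") == 1
  }, logical(1))
  if (any(!keep))
    warning(sum(!keep), " individual(s) missing one side: dropped")
  ids <- ids[keep]
  if (!length(ids)) stop("no individual has both sides")

  k <- dim(arr)[1]
  asym <- array(NA_real_, c(k, 2, length(ids)))
  sym <- array(NA_real_, c(k, 2, length(ids)))
  for (j in seq_along(ids)) {
    li <- which(individual == ids[j] & side == "left")
    ri <- which(individual == ids[j] & side == "right")
    asym[, , j] <- arr[, , li] - arr[, , ri]
    sym[, , j] <- (arr[, , li] + arr[, , ri]) / 2
  }
  da <- apply(asym, c(1, 2), mean)
  fa <- sweep(asym, c(1, 2), da)
  scores <- data.frame(
    individual = ids,
    fa_score = apply(fa, 3, function(m) sqrt(sum(m^2)))
  )
  cons <- apply(sym, c(1, 2), mean)
  cons <- cons / sqrt(sum(cons^2))
  structure(list(scores = scores, da = da, consensus_symmetric = cons,
                 asymmetry = asym), class = "fa_result")
}

#' Landmark FA scores for a cohort (per-sex Procrustes fits)
#'
#' Runs one generalized Procrustes fit per sex (male and female wing shapes
#' differ enough that a pooled consensus would leak shape dimorphism into
#' the asymmetry component), decomposes bilateral asymmetry within each fit,
#' and pools the FA scores into one response column.
#'
#' @param landmarks A data frame with columns `individual`, `side`
#'   (left/right), `sex` (optional), `lm` (landmark index 1..k), `x`, `y`.
#' @param by_sex Fit sexes separately (default) or pool.
#' @return A data frame `individual`, `sex`, `fa_score`.
#' @export
fa_scores <- function(landmarks, by_sex = TRUE) {
  stopifnot(all(c("individual", "side", "lm", "x", "y") %in% names(landmarks)))
  if (!("sex" %in% names(landmarks)) || !by_sex) landmarks$sex <- "all"
  out <- lapply(split(landmarks, landmarks$sex), function(df) {
    key <- interaction(df$individual, df$side, drop = TRUE)
    configs <- lapply(split(df[order(df$lm), ], key[order(df$lm)]),
                      function(s) cbind(s$x, s$y))
    meta <- do.call(rbind, lapply(split(df, key), function(s)
      data.frame(individual = s$individual[1], side = tolower(s$side[1]),
                 sex = s$sex[1])))
    fit <- gpa(configs, reflect = meta$side == "right")
    dec <- fa_decomposition(fit, meta$individual, meta$side)
    merge(dec$scores,
          unique(meta[, c("individual", "sex")]), by = "individual")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$individual), ]
}

#' Landmark table from synthetic wing pairs
#'
#' Collects the generator's 12-landmark configurations into the long format
#' consumed by [fa_scores()].
#'
#' @param pairs List of `wing_pair` objects.
#' @param sex Optional per-individual sex vector.
#' @return Long data frame `individual`, `side`, `sex`, `lm`, `x`, `y`.
#' @export
landmark_table <- function(pairs, sex = NULL) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    sx <- if (is.null(sex)) "all" else sex[i]
    do.call(rbind, lapply(c("left", "right"), function(sd) {
      lm <- p[[sd]]$landmarks
      data.frame(individual = i, side = sd, sex = sx,
                 lm = seq_len(nrow(lm)), x = lm[, 1], y = lm[, 2])
    }))
  })
  do.call(rbind, rows)
}
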