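# Image segmentation: binary wing raster -> WingGeometry (outline polygon,
# cell polygons, vein junctions). Coordinate convention: pixel origin at the
# image top-left with y down; converted to um with y flipped so anatomical
# "up" is +y.

#' Segment a wing image into outline, cells and junctions
#'
#' Binarizes the image (Otsu threshold, then morphological closing of radius
#' 1 px to seal single-pixel vein gaps), extracts membrane cells as interior
#' white connected components, the wing outline as the largest external
#' contour, and vein junctions as skeleton branch points (degree >= 3),
#' clustered within 3 px.
#'
#' @param image Numeric matrix in `[0, 1]` (1 = white background) or a
#'   `wing_image`; rows are image y (top to bottom).
#' @param scale_um_per_px Pixel size in um (> 0); taken from the image
#'   attribute when present.
#' @param side `"left"` or `"right"`.
#' @param wing_type `"front"` or `"hind"`.
#' @param drop_border_cells Discard cells whose polygon touches the image
#'   border (cut cells at the wing base).
#' @param min_cell_px Minimum cell size in pixels; smaller specks are
#'   discarded as noise.
#' @return A `wing_geometry` in um coordinates. When the image carries an
#'   `origin_um` attribute (images rendered in-session), coordinates are
#'   mapped back into the generating frame.
#' @examples
#' pair <- generate_wing_pair(synthetic_config(cells_target = 40), 1)
#' img <- render_wing_image(pair$left, scale_um_per_px = 60)
#' seg <- segment_wing(img, side = "left")
#' @export
segment_wing <- function(image, scale_um_per_px = NULL,
                         side = c("left", "right"),
                         wing_type = c("front", "hind"),
                         drop_border_cells = TRUE, min_cell_px = 4L) {
  side <- match.arg(side)
  wing_type <- match.arg(wing_type)
  if (is.null(scale_um_per_px)) scale_um_per_px <- attr(image, "scale_um_per_px")
  stopifnot(is.numeric(scale_um_per_px), scale_um_per_px > 0)
  img <- unclass(image)
  attributes(img) <- list(dim = dim(img))
  h <- nrow(img); w <- ncol(img)

  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  veins <- img < thr
  if (!any(veins)) stop("open wing boundary: no vein pixels found")
  veins <- EBImage::closing(veins * 1, EBImage::makeBrush(3, "box")) > 0

  filled <- EBImage::fillHull(veins * 1) > 0
  lab_wing <- EBImage::bwlabel(filled * 1)
  if (max(lab_wing) == 0) stop("open wing boundary: nothing to segment")
  sizes <- tabulate(lab_wing[lab_wing > 0])
  wing_id <- which.max(sizes)
  wing_mask <- lab_wing == wing_id

  interior <- wing_mask & !veins
  if (!any(interior)) stop("open wing boundary: no enclosed cells (zero cells)")
  lab <- EBImage::bwlabel(interior * 1)

  # um mapping (y flipped); honors the render origin when available
  org <- attr(image, "origin_um")
  if (is.null(org)) org <- c(x = 0, y = (h - 1) * scale_um_per_px)
  px_to_um <- function(rc) {  # rc: matrix [row, col], 1-based pixel centres
    cbind(org[[1]] + (rc[, 2] - 1) * scale_um_per_px,
          org[[2]] - (rc[, 1] - 1) * scale_um_per_px)
  }

  # outline: largest external contour (EBImage traces 0-based [dim1 dim2])
  oc_w <- EBImage::ocontour(EBImage::Image(wing_mask * 1))
  outline_px <- oc_w[[which.max(vapply(oc_w, nrow, integer(1)))]] + 1
  outline <- px_to_um(outline_px)
  if (poly_signed_area(outline) < 0) outline <- outline[rev(seq_len(nrow(outline))), ]

  # cells
  oc <- EBImage::ocontour(EBImage::Image(lab))
  npix <- tabulate(lab[lab > 0])
  cells <- list()
  cid <- 0L
  for (k in seq_along(oc)) {
    if (npix[k] < min_cell_px) next
    cpx <- oc[[k]] + 1
    if (drop_border_cells &&
        (min(cpx) <= 1 || max(cpx[, 1]) >= h || max(cpx[, 2]) >= w)) next
    poly <- dedup_poly(px_to_um(cpx))
    if (nrow(poly) < 3 || poly_area(poly) <= 0) next
    cid <- cid + 1L
    cells[[cid]] <- list(id = cid, vertices = poly, set_label = NA_integer_)
  }
  if (!length(cells)) stop("zero cells after border filtering")

  # junctions: skeleton branch points clustered within 3 px
  skel <- zs_thin(veins)
  nb <- neighbor_transitions(skel)
  bp <- which(skel & nb >= 3, arr.ind = TRUE)
  if (nrow(bp) == 0) {
    junct <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        degree = integer(0))
  } else if (nrow(bp) == 1) {
    um <- px_to_um(bp)
    junct <- data.frame(id = 1L, x = um[, 1], y = um[, 2],
                        degree = nb[bp] )
  } else {
    cl <- cutree(hclust(dist(bp), method = "single"), h = 3)
    um <- px_to_um(bp)
    deg <- nb[bp]
    junct <- do.call(rbind, lapply(split(seq_along(cl), cl), function(ix) {
      data.frame(x = mean(um[ix, 1]), y = mean(um[ix, 2]),
                 degree = max(deg[ix]))
    }))
    junct <- data.frame(id = seq_len(nrow(junct)), junct, row.names = NULL)
  }

  new_wing_geometry(side, wing_type, outline, cells, junct,
                    scale_um_per_px = scale_um_per_px)
}

# Zhang-Suen thinning of a logical matrix, vectorized over pixels.
zs_thin <- function(m, max_iter = 200L) {
  m <- m > 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(p, dr, dc) p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (sub in 1:2) {
      p <- pad[2:(h + 1), 2:(w + 1)]
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1);  p6 <- shift(pad, 1, 0);  p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- p & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- p & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        p[cond] <- FALSE
        pad[2:(h + 1), 2:(w + 1)] <- p
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)]
}

# Number of 0->1 transitions in the circular 8-neighbour sequence. This is
# the skeleton branch multiplicity: 2 along a line (including staircase
# corners, which a plain neighbour count overcounts), >= 3 at junctions.
neighbor_transitions <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m > 0
  sh <- function(dr, dc) pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  # circular order p2..p9: N, NE, E, SE, S, SW, W, NW
  nb <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
             sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  tr <- matrix(0L, h, w)
  for (k in 1:8) tr <- tr + (!nb[[k]] & nb[[if (k == 8) 1 else k + 1]])
  tr
}

# 8-neighbour count of TRUE pixels.
neighbor_count <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m * 1L
  out <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out
}

#' Assign proximal/distal section labels to cells
#'
#' Splits the wing into Set 1 (proximal) and Set 2 (distal) at a given x
#' position, with the full cell column containing the split included in
#' Set 1. If no cell spans `split_x`, the nearest cell column is used.
#'
#' @param wing A `wing_geometry`.
#' @param split_x Split position on the wing x axis (um); e.g. the branching
#'   of the second and third radius, or landmark 8.
#' @return The wing with `set_label` filled in (1 = proximal, 2 = distal)
#'   for every cell.
#' @export
assign_sets <- function(wing, split_x) {
  if (!length(wing$cells)) return(wing)
  xr <- t(vapply(wing$cells, function(cl) range(cl$vertices[, 1]), numeric(2)))
  cx <- vapply(wing$cells, function(cl) poly_centroid(cl$vertices)[1], numeric(1))
  covering <- which(xr[, 1] <= split_x & xr[, 2] >= split_x)
  if (!length(covering)) {
    d <- pmax(xr[, 1] - split_x, split_x - xr[, 2])
    seedc <- which.min(d)
    covering <- which(xr[, 1] < xr[seedc, 2] & xr[, 2] > xr[seedc, 1])
  }
  boundary <- max(cx[covering])
  eps <- 1e-9 * max(1, abs(boundary))
  for (i in seq_along(wing$cells)) {
    wing$cells[[i]]$set_label <- if (cx[i] <= boundary + eps) 1L else 2L
  }
  wing
}
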