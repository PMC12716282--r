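# Per-cell and whole-wing geometric descriptors.

#' Geometric features of a single membrane cell
#'
#' Area and perimeter by the shoelace/edge-sum formulas, length and width as
#' extents along the principal axes of the vertex cloud (rotation
#' invariant), circularity as the isoperimetric quotient `4*pi*A/P^2`.
#'
#' @param cell A cell entry of a `wing_geometry` (list with `id`,
#'   `vertices`), or a bare n x 2 vertex matrix.
#' @return A one-row data frame: `cell_id`, `area` (um^2), `perimeter` (um),
#'   `length`, `width` (um), `circularity`, `centroid_x`, `centroid_y` (um),
#'   `set_label`.
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
#' cell_features(sq)  # area 1, perimeter 4, circularity pi/4
#' @export
cell_features <- function(cell) {
  if (is.matrix(cell)) cell <- list(id = NA_integer_, vertices = cell, set_label = NA_integer_)
  v <- cell$vertices
  a <- poly_area(v)
  if (a <= 0) stop("degenerate cell polygon (zero area)")
  p <- poly_perimeter(v)
  ext <- principal_extents(v)
  ctr <- poly_centroid(v)
  data.frame(cell_id = cell$id, area = a, perimeter = p,
             length = ext[["length"]], width = ext[["width"]],
             circularity = 4 * pi * a / p^2,
             centroid_x = ctr[1], centroid_y = ctr[2],
             set_label = if (is.null(cell$set_label)) NA_integer_ else cell$set_label)
}

#' Feature table for all cells of a wing
#'
#' @param wing A `wing_geometry`.
#' @return A data frame with one [cell_features()] row per cell.
#' @export
cell_features_table <- function(wing) {
  n <- length(wing$cells)
  if (!n) {
    return(cell_features(matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE))[0, ])
  }
  m <- matrix(NA_real_, n, 7)
  ids <- numeric(n)
  sets <- integer(n)
  for (i in seq_len(n)) {
    cl <- wing$cells[[i]]
    v <- cl$vertices
    a <- poly_area(v)
    if (a <= 0) stop("degenerate cell polygon (zero area)")
    p <- poly_perimeter(v)
    ext <- principal_extents(v)
    ctr <- poly_centroid(v)
    m[i, ] <- c(a, p, ext[["length"]], ext[["width"]], 4 * pi * a / p^2,
                ctr[1], ctr[2])
    ids[i] <- as.numeric(cl$id)
    sets[i] <- if (is.null(cl$set_label) || is.na(cl$set_label)) NA_integer_
    else as.integer(cl$set_label)
  }
  data.frame(cell_id = ids, area = m[, 1], perimeter = m[, 2],
             length = m[, 3], width = m[, 4], circularity = m[, 5],
             centroid_x = m[, 6], centroid_y = m[, 7], set_label = sets)
}

#' Whole-wing geometric features
#'
#' Wing area/perimeter from the outline polygon, length/width as
#' principal-axis extents of the outline, plus cell and junction counts.
#'
#' @param wing A `wing_geometry`.
#' @return A one-row data frame: `area` (um^2), `perimeter`, `length`,
#'   `width` (um), `n_cells`, `n_junctions`.
#' @export
wing_features <- function(wing) {
  sz <- outline_size(wing$outline)
  data.frame(area = sz[["area"]], perimeter = sz[["perimeter"]],
             length = sz[["length"]], width = sz[["width"]],
             n_cells = length(wing$cells), n_junctions = nrow(wing$junctions))
}

#' Wing load
#'
#' Adult wet weight divided by the mean wing area of a pair (front or hind),
#' giving two values per individual.
#'
#' @param wet_weight_mg Adult wet weight (mg, > 0).
#' @param mean_wing_area_mm2 Mean of left and right wing area (mm^2, > 0).
#' @return Wing load in mg/mm^2.
#' @examples
#' wing_load(40, 100)  # 0.4
#' @export
wing_load <- function(wet_weight_mg, mean_wing_area_mm2) {
  if (any(wet_weight_mg <= 0) || any(mean_wing_area_mm2 <= 0))
    stop("wet weight and wing area must be positive")
  wet_weight_mg / mean_wing_area_mm2
}
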