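# Rasterization of wing geometries: veins dark on white, following the
# photographic convention of maximum vein/background contrast.

#' Render a wing geometry to a binary raster image
#'
#' Draws the outline and every cell edge as dark veins on a white background.
#' With a vein width below the smallest cell thickness, every ground-truth
#' cell maps to exactly one white connected component.
#'
#' @param wing A `wing_geometry`.
#' @param scale_um_per_px Physical size of one pixel (um); must be > 0.
#' @param vein_width_px Vein stroke width in pixels (>= 1; even values are
#'   rounded up to the next odd width).
#' @param margin_px White margin around the wing bounding box.
#' @return A numeric matrix (rows = image y, top to bottom; 1 = white
#'   background, 0 = vein) of class `wing_image`, with attributes
#'   `scale_um_per_px` and `origin_um` (the um coordinates of the pixel
#'   (1,1) centre) that allow exact back-transformation.
#' @examples
#' pair <- generate_wing_pair(synthetic_config(cells_target = 40), 1)
#' img <- render_wing_image(pair$left, scale_um_per_px = 50)
#' @export
render_wing_image <- function(wing, scale_um_per_px, vein_width_px = 1L,
                              margin_px = 5L) {
  stopifnot(scale_um_per_px > 0, vein_width_px >= 1)
  segs <- geometry_segments(wing)
  xr <- range(segs[, c(1, 3)]); yr <- range(segs[, c(2, 4)])
  w <- ceiling(diff(xr) / scale_um_per_px) + 2 * margin_px + 1
  h <- ceiling(diff(yr) / scale_um_per_px) + 2 * margin_px + 1
  # pixel (row r, col c) centre is at
  #   x = xr[1] + (c - 1 - margin) * scale,  y = yr[2] - (r - 1 - margin) * scale
  to_col <- function(x) (x - xr[1]) / scale_um_per_px + margin_px + 1
  to_row <- function(y) (yr[2] - y) / scale_um_per_px + margin_px + 1

  mask <- matrix(FALSE, h, w)
  len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  npt <- pmax(2L, ceiling(len / (0.4 * scale_um_per_px)))
  for (i in seq_len(nrow(segs))) {
    t_ <- seq(0, 1, length.out = npt[i])
    cc <- round(to_col(segs[i, 1] + t_ * (segs[i, 3] - segs[i, 1])))
    rr <- round(to_row(segs[i, 2] + t_ * (segs[i, 4] - segs[i, 2])))
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  vw <- as.integer(vein_width_px)
  if (vw %% 2 == 0) vw <- vw + 1L
  if (vw > 1) {
    mask <- EBImage::dilate(mask * 1, EBImage::makeBrush(vw, "disc")) > 0
  }
  # lossy-case warning: cells thinner than the stroke may vanish
  if (length(wing$cells)) {
    wmin <- min(vapply(wing$cells,
                       function(cl) principal_extents(cl$vertices)[["width"]],
                       numeric(1)))
    if (wmin < (vw + 1) * scale_um_per_px)
      warning("vein width is close to the thinnest cell; cells may vanish in the raster")
  }
  img <- 1 - mask * 1
  attr(img, "scale_um_per_px") <- scale_um_per_px
  attr(img, "origin_um") <- c(x = xr[1] - margin_px * scale_um_per_px,
                              y = yr[2] + margin_px * scale_um_per_px)
  class(img) <- c("wing_image", class(img))
  img
}

geometry_segments <- function(wing) {
  polys <- c(list(wing$outline), lapply(wing$cells, `[[`, "vertices"))
  do.call(rbind, lapply(polys, function(p) {
    n <- nrow(p)
    cbind(p, p[c(2:n, 1), , drop = FALSE])
  }))
}

#' Write a wing image as a PNG file
#'
#' @param img A `wing_image` matrix from [render_wing_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wing_png <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' Read a grayscale wing image from PNG
#'
#' Color images are converted to grayscale by channel averaging.
#'
#' @param path PNG file path.
#' @param scale_um_per_px Pixel size (um) to attach to the image.
#' @return A `wing_image` matrix (1 = white).
#' @export
read_wing_png <- function(path, scale_um_per_px = NA_real_) {
  a <- png::readPNG(path)
  img <- if (length(dim(a)) == 3) apply(a[, , 1:3, drop = FALSE], c(1, 2), mean) else a
  attr(img, "scale_um_per_px") <- scale_um_per_px
  class(img) <- c("wing_image", class(img))
  img
}
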