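# Synthetic wing-pair and cohort generator. Emulates the data structure of a
# paired-wing FA study: a deformed rectangular lattice of membrane cells
# clipped to a convex elliptical-teardrop outline (damselfly-like), with
# per-side Gaussian developmental noise on vein junctions, optional
# directional offsets, cell-count perturbations (merges), and cohort-level
# treatment effects on size and asymmetry. Geometry is metric (um).

#' Configuration for the synthetic wing generator
#'
#' Bundles every tunable of the generator. Defaults describe a plausible
#' damselfly-scale study condition; see the methods vignette for the
#' rationale behind each value.
#'
#' @param n_individuals Number of individuals in a cohort.
#' @param cells_target Approximate number of membrane cells per wing (>= 4).
#' @param outline_length_mm Wing length (tip to base) in mm.
#' @param outline_aspect Length / width ratio of the wing outline.
#' @param fa_position_sd_um Per-side Gaussian jitter SD (um) applied to vein
#'   junction positions; the fluctuating-asymmetry position channel.
#' @param fa_shape_sd Per-cell edge perturbation expressed as a fraction of
#'   the local lattice spacing; the FA shape channel (applied as additional
#'   junction-level jitter so that cells follow their junctions and the
#'   tessellation stays gap-free).
#' @param fa_outline_sd_um Per-side smooth outline perturbation SD (um), the
#'   wing-size FA channel; `NULL` (default) ties it to `fa_position_sd_um`.
#' @param directional_offset_um Length-2 vector; constant translation (um)
#'   added to every right-wing junction after mirroring (directional
#'   asymmetry channel).
#' @param antisymmetry Logical; if `TRUE` the directional offset is applied
#'   with a random sign per individual (antisymmetry mode for the
#'   symmetry-type screening test).
#' @param count_perturb_prob Probability that a wing undergoes one cell merge
#'   (two adjacent cells fuse), perturbing cell/junction counts.
#' @param fa_region Region receiving *extra* positional noise:
#'   `"all"`, `"proximal"` or `"distal"`.
#' @param fa_region_extra_sd_um Extra jitter SD (um) applied only inside
#'   `fa_region` (on top of the uniform baseline channels).
#' @param size_cv Between-individual coefficient of variation of wing size
#'   (lognormal multiplier on `outline_length_mm`).
#' @param effect_map Named list: one entry per design factor, each a named
#'   numeric vector of multipliers on config parameters, e.g.
#'   `list(hydrology = c(outline_length_mm = 1.25))`. Binary factors apply
#'   the multiplier at level 1; numeric factors (doses) apply
#'   `multiplier^(value/max(value))`.
#' @param sex_effect Multiplier on wing size and body weight for males
#'   (females are the reference).
#' @param wet_weight_mg Mean adult wet weight (mg, lognormal).
#' @param wet_weight_cv CV of adult wet weight.
#' @param wet_weight_gain_mg Mean larval wet-weight gain (mg, lognormal).
#' @param days_to_emergence_mean Mean days until emergence (Poisson).
#' @param seed Master seed; identical configs yield bit-identical cohorts.
#' @param n_outline_vertices Number of vertices of the outline polygon.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_individuals = 4, cells_target = 40, seed = 7)
#' pair <- generate_wing_pair(cfg, 1)
#' @export
synthetic_config <- function(n_individuals = 80L,
                             cells_target = 250L,
                             outline_length_mm = 20,
                             outline_aspect = 4,
                             fa_position_sd_um = 50,
                             fa_shape_sd = 0.02,
                             fa_outline_sd_um = NULL,
                             directional_offset_um = c(0, 0),
                             antisymmetry = FALSE,
                             count_perturb_prob = 0.3,
                             fa_region = c("all", "proximal", "distal"),
                             fa_region_extra_sd_um = 0,
                             size_cv = 0.05,
                             effect_map = list(),
                             sex_effect = 0.95,
                             wet_weight_mg = 25,
                             wet_weight_cv = 0.15,
                             wet_weight_gain_mg = 8,
                             days_to_emergence_mean = 28,
                             seed = 1L,
                             n_outline_vertices = 48L) {
  fa_region <- match.arg(fa_region)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    cells_target = as.integer(cells_target),
    outline_length_mm = outline_length_mm,
    outline_aspect = outline_aspect,
    fa_position_sd_um = fa_position_sd_um,
    fa_shape_sd = fa_shape_sd,
    fa_outline_sd_um = fa_outline_sd_um,
    directional_offset_um = as.numeric(directional_offset_um),
    antisymmetry = isTRUE(antisymmetry),
    count_perturb_prob = count_perturb_prob,
    fa_region = fa_region,
    fa_region_extra_sd_um = fa_region_extra_sd_um,
    size_cv = size_cv,
    effect_map = effect_map,
    sex_effect = sex_effect,
    wet_weight_mg = wet_weight_mg,
    wet_weight_cv = wet_weight_cv,
    wet_weight_gain_mg = wet_weight_gain_mg,
    days_to_emergence_mean = days_to_emergence_mean,
    seed = as.integer(seed),
    n_outline_vertices = as.integer(n_outline_vertices)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    cfg$n_individuals >= 0,
    cfg$cells_target >= 4,
    cfg$outline_length_mm > 0,
    cfg$outline_aspect > 0,
    cfg$fa_position_sd_um >= 0,
    cfg$fa_shape_sd >= 0,
    is.null(cfg$fa_outline_sd_um) || cfg$fa_outline_sd_um >= 0,
    length(cfg$directional_offset_um) == 2,
    cfg$count_perturb_prob >= 0, cfg$count_perturb_prob <= 1,
    cfg$fa_region_extra_sd_um >= 0,
    cfg$size_cv >= 0,
    cfg$sex_effect > 0,
    cfg$wet_weight_mg > 0,
    cfg$n_outline_vertices >= 12
  )
  for (e in cfg$effect_map) stopifnot(is.numeric(e), !is.null(names(e)), all(e > 0))
  invisible(cfg)
}

# Evaluate expr with a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-style per-individual seed derived from the master seed.
ind_seed <- function(master, index, salt = 0) {
  as.integer((as.double(master) %% 2147483629 * 48271 +
                as.double(index) * 2147483 +
                as.double(salt) * 1000003 + 7919) %% 2147483629) + 1L
}

# Convex elliptical-teardrop outline polygon (CCW), centered at the origin,
# wing base at -x, tip at +x, slightly wider distally, with a flattened
# upper edge (the nearly straight costa of odonate wings; also what makes
# the common-frame rotation identifiable).
wing_outline_polygon <- function(length_um, aspect, n = 48, taper = 0.12) {
  outline_point(seq(0, 2 * pi, length.out = n + 1)[-(n + 1)],
                length_um, aspect, taper = taper)
}

# Evaluate the outline point at arbitrary parameter t with a per-side
# harmonic radial perturbation (amp, phase vectors; may be zero-length).
outline_point <- function(t, length_um, aspect, amp = numeric(0),
                          phase = numeric(0), taper = 0.12, flatten = 2.2) {
  a <- length_um / 2
  b <- length_um / (2 * aspect)
  s <- sin(t)
  up <- s > 0
  s[up] <- tanh(flatten * s[up]) / tanh(flatten)  # flattened leading edge
  p <- cbind(a * cos(t), b * s * (1 + taper * cos(t)))
  if (length(amp)) {
    rho <- sqrt(rowSums(p^2))
    f <- rep(0, length(t))
    for (k in seq_along(amp)) f <- f + amp[k] * sin(k * t + phase[k])
    p <- p * (1 + f / rho)
  }
  p
}

# Individual-level wing template: deformed rectangular lattice over the
# outline bounding box. Node deformation is smooth and shared by both sides;
# it represents true venation geometry, not asymmetry.
build_template <- function(cfg_i) {
  length_um <- cfg_i$outline_length_mm * 1000
  outline0 <- wing_outline_polygon(length_um, cfg_i$outline_aspect,
                                   cfg_i$n_outline_vertices)
  xr <- range(outline0[, 1]); yr <- range(outline0[, 2])
  Lx <- diff(xr); Ly <- diff(yr)
  fill <- poly_area(outline0) / (Lx * Ly)
  n_cells <- cfg_i$cells_target
  nyc <- max(2L, as.integer(round(sqrt(n_cells / fill / (Lx / Ly)))))
  nxc <- max(2L, as.integer(round(n_cells / fill / nyc)))
  # pad the lattice beyond the bbox by more than the maximum warp
  # displacement (2 * 0.18 * spacing) so warped boundary rows still cover
  # the outline interior completely
  sx <- Lx / nxc; sy <- Ly / nyc
  gx <- seq(xr[1] - 0.55 * sx, xr[2] + 0.55 * sx, length.out = nxc + 1)
  gy <- seq(yr[1] - 0.55 * sy, yr[2] + 0.55 * sy, length.out = nyc + 1)
  nodes <- cbind(rep(gx, times = nyc + 1), rep(gy, each = nxc + 1))
  spacing <- mean(c(diff(gx)[1], diff(gy)[1]))

  # smooth deterministic warp (8 coefficients from the individual stream)
  w <- runif(8)
  u <- (nodes[, 1] - xr[1]) / Lx
  v <- (nodes[, 2] - yr[1]) / Ly
  A <- 0.18 * spacing
  nodes[, 1] <- nodes[, 1] + A * ((0.3 + 0.7 * w[1]) * sin(pi * u + 2 * pi * w[2]) +
                                    (0.3 + 0.7 * w[3]) * sin(2 * pi * v + 2 * pi * w[4]))
  nodes[, 2] <- nodes[, 2] + A * ((0.3 + 0.7 * w[5]) * sin(pi * v + 2 * pi * w[6]) +
                                    (0.3 + 0.7 * w[7]) * sin(2 * pi * u + 2 * pi * w[8]))

  nid <- function(i, j) (j - 1L) * (nxc + 1L) + i
  ij <- expand.grid(i = seq_len(nxc), j = seq_len(nyc))
  quads <- cbind(nid(ij$i, ij$j), nid(ij$i + 1L, ij$j),
                 nid(ij$i + 1L, ij$j + 1L), nid(ij$i, ij$j + 1L))
  list(length_um = length_um, aspect = cfg_i$outline_aspect,
       outline0 = outline0, nodes = nodes, quads = quads,
       nxc = nxc, nyc = nyc, spacing = spacing,
       cell_i = ij$i, cell_j = ij$j)
}

# Per-side realization: jittered nodes, perturbed outline, inclusion set,
# optional merge; full polygon construction only when detail == "geometry".
realize_side <- function(tpl, cfg_i, merge_now, detail = "geometry") {
  n_nodes <- nrow(tpl$nodes)
  sd_shape <- cfg_i$fa_shape_sd * tpl$spacing
  sd_base <- sqrt(cfg_i$fa_position_sd_um^2 + sd_shape^2)
  jit <- matrix(rnorm(2 * n_nodes), n_nodes, 2) * sd_base
  extra <- matrix(rnorm(2 * n_nodes), n_nodes, 2) * cfg_i$fa_region_extra_sd_um
  if (cfg_i$fa_region_extra_sd_um > 0) {
    in_region <- switch(cfg_i$fa_region,
                        all = rep(TRUE, n_nodes),
                        proximal = tpl$nodes[, 1] < 0,
                        distal = tpl$nodes[, 1] > 0)
    jit <- jit + extra * in_region
  }
  nodes <- tpl$nodes + jit

  # smooth low-order outline perturbation; boundary displacement RMS of
  # roughly the outline channel SD / sqrt(2)
  K <- 3L
  out_sd <- if (is.null(cfg_i$fa_outline_sd_um)) cfg_i$fa_position_sd_um
  else cfg_i$fa_outline_sd_um
  amp <- rnorm(K, 0, out_sd / sqrt(K))
  phase <- runif(K, 0, 2 * pi)
  nt <- cfg_i$n_outline_vertices
  tt <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
  outline <- outline_point(tt, tpl$length_um, tpl$aspect, amp, phase)

  # inclusion: a lattice cell belongs to the wing if its template centroid
  # or any template corner node lies strictly inside the side's outline.
  # Membership is decided on the noise-free template positions: positional
  # jitter moves cells, it does not create or destroy them (cell-count
  # asymmetry has its own channels: merges and the outline perturbation).
  node_in <- points_in_convex(tpl$nodes, outline)
  cent <- (tpl$nodes[tpl$quads[, 1], ] + tpl$nodes[tpl$quads[, 2], ] +
             tpl$nodes[tpl$quads[, 3], ] + tpl$nodes[tpl$quads[, 4], ]) / 4
  cent_in <- points_in_convex(cent, outline)
  corner_in <- node_in[tpl$quads[, 1]] | node_in[tpl$quads[, 2]] |
    node_in[tpl$quads[, 3]] | node_in[tpl$quads[, 4]]
  included <- which(cent_in | corner_in)

  # optional merge of two adjacent included cells (count perturbation)
  merged_pair <- NULL
  if (merge_now && length(included) > 4) {
    iid <- sample(included)
    for (q in iid) {
      nb <- q + 1L  # right lattice neighbour
      if (tpl$cell_i[q] < tpl$nxc && (nb %in% included)) {
        merged_pair <- c(q, nb); break
      }
    }
  }

  out <- list(nodes = nodes, outline = outline, included = included,
              merged_pair = merged_pair, amp = amp, phase = phase)

  # junction degrees: number of included cells (merged pair counts once)
  inc_eff <- included
  quads_eff <- tpl$quads[included, , drop = FALSE]
  deg <- tabulate(as.vector(quads_eff), nbins = n_nodes)
  if (!is.null(merged_pair)) {
    # the two shared nodes of the merged pair lose one incidence
    shared <- intersect(tpl$quads[merged_pair[1], ], tpl$quads[merged_pair[2], ])
    deg[shared] <- deg[shared] - 1L
  }
  out$degree <- deg
  out$junction_ids <- which(deg >= 3L)
  out$n_cells <- length(included) - as.integer(!is.null(merged_pair))
  out$n_junctions <- length(out$junction_ids)

  if (detail == "geometry") {
    out$cells <- build_side_cells(tpl, nodes, outline, included, merged_pair)
    # geometry detail counts actual cells: boundary slivers below the
    # resolvable-area threshold are dropped by build_side_cells
    out$n_cells <- length(out$cells)
  }
  out
}

build_side_cells <- function(tpl, nodes, outline, included, merged_pair) {
  node_in <- points_in_convex(nodes, outline)
  cells <- vector("list", length(included))
  keep <- rep(TRUE, length(included))
  skip <- if (is.null(merged_pair)) integer(0) else merged_pair
  k <- 0L
  for (q in included) {
    k <- k + 1L
    if (q %in% skip) { keep[k] <- q == merged_pair[1]; if (!keep[k]) next }
    if (!is.null(merged_pair) && q == merged_pair[1]) {
      a <- merged_pair[1]; b <- merged_pair[2]
      vid <- c(tpl$quads[a, 1], tpl$quads[a, 2], tpl$quads[b, 2],
               tpl$quads[b, 3], tpl$quads[a, 3], tpl$quads[a, 4])
      id <- -a  # negative id marks a merged (count-perturbed) cell
    } else {
      vid <- tpl$quads[q, ]
      id <- q
    }
    poly <- nodes[vid, , drop = FALSE]
    if (!all(node_in[vid])) {
      poly <- convex_clip(poly, outline)
      poly <- dedup_poly(poly)
    }
    if (nrow(poly) < 3 || poly_area(poly) < 1e-6 * tpl$spacing^2) {
      keep[k] <- FALSE
      next
    }
    cells[[k]] <- list(id = id, vertices = poly, set_label = NA_integer_)
  }
  cells[keep & !vapply(cells, is.null, logical(1))]
}

# Twelve landmark anchors: 7 on the outline (parameter t), 5 in the interior
# (fractions of the half-length/half-width). Loosely follow the odonate
# scheme: antenodal crossveins, anal branch, nodus, cubital vein, medial
# branches, pterostigma edges.
landmark_anchors <- function() {
  list(
    list(type = "outline", t = 0.82 * pi),   # 1 antenodal crossvein a
    list(type = "outline", t = 0.74 * pi),   # 2 antenodal crossvein b
    list(type = "outline", t = 1.22 * pi),   # 3 anal vein branch
    list(type = "outline", t = 0.50 * pi),   # 4 nodus
    list(type = "interior", u = -0.35, v = 0.30),  # 5 second radius
    list(type = "interior", u = 0.05, v = 0.35),   # 6 second radius
    list(type = "outline", t = 1.50 * pi),   # 7 cubital vein
    list(type = "interior", u = -0.10, v = -0.15), # 8 medial branch
    list(type = "interior", u = 0.25, v = -0.10),  # 9 medial branch
    list(type = "interior", u = 0.55, v = 0.05),   # 10 medial branch
    list(type = "outline", t = 0.16 * pi),   # 11 pterostigma outer
    list(type = "outline", t = 0.08 * pi)    # 12 pterostigma inner
  )
}

realize_landmarks <- function(tpl, side_real, cfg_i) {
  an <- landmark_anchors()
  a <- tpl$length_um / 2
  b <- tpl$length_um / (2 * tpl$aspect)
  lm <- matrix(NA_real_, 12, 2)
  for (i in seq_along(an)) {
    d <- an[[i]]
    if (d$type == "outline") {
      lm[i, ] <- outline_point(d$t, tpl$length_um, tpl$aspect,
                               side_real$amp, side_real$phase)
    } else {
      lm[i, ] <- c(d$u * a, d$v * b)
    }
  }
  lm + matrix(rnorm(24), 12, 2) * cfg_i$fa_position_sd_um
}

new_wing_geometry <- function(side, wing_type, outline, cells, junct_df,
                              landmarks = NULL, scale_um_per_px = NA_real_) {
  structure(list(side = side, wing_type = wing_type, outline = outline,
                 cells = cells, junctions = junct_df, landmarks = landmarks,
                 scale_um_per_px = scale_um_per_px),
            class = "wing_geometry")
}

#' @export
print.wing_geometry <- function(x, ...) {
  cat(sprintf("<wing_geometry> %s %s wing: %d cells, %d junctions, outline of %d vertices\n",
              x$side, x$wing_type, length(x$cells), nrow(x$junctions),
              nrow(x$outline)))
  invisible(x)
}

# Reflect across the vertical axis. Vertex order is deliberately preserved
# (rings change handedness): IEEE negation is exact, so a mirrored copy
# stays bitwise symmetric to its source — downstream consumers are
# orientation-agnostic, and the noise-free mirror identity stays exact.
mirror_geometry <- function(g) {
  g$outline <- reflect_x(g$outline)
  g$cells <- lapply(g$cells, function(cl) {
    cl$vertices <- reflect_x(cl$vertices)
    cl
  })
  g$junctions$x <- -g$junctions$x
  if (!is.null(g$landmarks)) g$landmarks <- reflect_x(g$landmarks)
  g
}

#' Generate one synthetic left/right wing pair with ground truth
#'
#' The right wing is a mirrored copy of the same underlying wing template
#' with its own independent developmental noise. Ground truth records the
#' cell and junction correspondence between sides.
#'
#' @param config A [synthetic_config()].
#' @param individual_index Integer; selects the individual's private RNG
#'   stream from the master seed.
#' @param force_merge `"none"`, `"left"` or `"right"`: force (exactly one)
#'   cell merge on that side regardless of `count_perturb_prob`; test and
#'   demonstration plumbing.
#' @param detail `"geometry"` builds full cell polygons; `"counts"` only
#'   realizes outlines, inclusion counts and junction degrees (fast path for
#'   large simulations that need size and count variables only); `"sizes"`
#'   realizes outlines only (size variables, no tessellation).
#'
#' @return A list of class `wing_pair` with elements `left`, `right`
#'   ([wing_geometry][new_wing_geometry] objects; `NULL` cells in counts
#'   detail) and `truth` (correspondence ids, per-side node positions in the
#'   shared template frame, merge records, injected-region label, realized
#'   size multiplier).
#' @examples
#' pair <- generate_wing_pair(synthetic_config(cells_target = 60), 1)
#' pair$left
#' @export
generate_wing_pair <- function(config, individual_index = 1L,
                               force_merge = c("auto", "none", "left", "right"),
                               detail = c("geometry", "counts", "sizes")) {
  validate_synthetic_config(config)
  force_merge <- match.arg(force_merge)
  detail <- match.arg(detail)
  for (attempt in 0:9) {
    res <- try(with_seed(
      ind_seed(config$seed, individual_index, attempt),
      realize_pair(config, force_merge, detail)
    ), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("degenerate tessellation: failed to generate a valid wing pair after 10 attempts (",
       attr(res, "condition")$message, ")")
}

realize_pair <- function(config, force_merge, detail) {
  cfg_i <- config
  size_mult <- if (config$size_cv > 0)
    rlnorm(1, -config$size_cv^2 / 2, config$size_cv) else 1
  cfg_i$outline_length_mm <- config$outline_length_mm * size_mult

  if (detail == "sizes") return(realize_pair_sizes(cfg_i, config, size_mult))
  tpl <- build_template(cfg_i)

  merge_left <- switch(force_merge,
                       auto = runif(1) < cfg_i$count_perturb_prob,
                       left = TRUE, none = FALSE, right = FALSE)
  merge_right <- switch(force_merge,
                        auto = runif(1) < cfg_i$count_perturb_prob,
                        right = TRUE, none = FALSE, left = FALSE)

  L <- realize_side(tpl, cfg_i, merge_left, detail)
  R <- realize_side(tpl, cfg_i, merge_right, detail)
  lmL <- realize_landmarks(tpl, L, cfg_i)
  lmR <- realize_landmarks(tpl, R, cfg_i)

  anti_sign <- if (config$antisymmetry) sample(c(-1, 1), 1) else 1
  offset <- config$directional_offset_um * anti_sign

  gL <- side_to_geometry(L, "left", detail)
  gL$landmarks <- lmL
  gR <- side_to_geometry(R, "right", detail)
  gR$landmarks <- lmR
  gR <- mirror_geometry(gR)
  gR <- translate_geometry(gR, offset)

  common_cells <- if (detail == "geometry") {
    intersect(vapply(gL$cells, function(cl) as.numeric(cl$id), numeric(1)),
              vapply(gR$cells, function(cl) as.numeric(cl$id), numeric(1)))
  } else intersect(L$included, R$included)
  drop_ids <- c(L$merged_pair, R$merged_pair, common_cells[common_cells < 0])
  truth <- list(
    cell_ids = setdiff(common_cells, drop_ids),
    junction_ids = intersect(L$junction_ids, R$junction_ids),
    merged_left = L$merged_pair, merged_right = R$merged_pair,
    nodes_left = L$nodes, nodes_right = R$nodes,  # shared template frame
    region = if (config$fa_region_extra_sd_um > 0) config$fa_region else "none",
    size_mult = size_mult,
    directional_offset = offset
  )
  structure(list(left = gL, right = gR, truth = truth), class = "wing_pair")
}

# Outline-only realization: size variables without tessellation.
realize_pair_sizes <- function(cfg_i, config, size_mult) {
  length_um <- cfg_i$outline_length_mm * 1000
  nt <- cfg_i$n_outline_vertices
  tt <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
  one_side <- function(side) {
    K <- 3L
    out_sd <- if (is.null(cfg_i$fa_outline_sd_um)) cfg_i$fa_position_sd_um
    else cfg_i$fa_outline_sd_um
    amp <- rnorm(K, 0, out_sd / sqrt(K))
    phase <- runif(K, 0, 2 * pi)
    outline <- outline_point(tt, length_um, cfg_i$outline_aspect, amp, phase)
    g <- new_wing_geometry(side, "front", outline, list(),
                           data.frame(id = integer(0), x = numeric(0),
                                      y = numeric(0), degree = integer(0)))
    g$n_cells_truth <- NA_real_
    g
  }
  gL <- one_side("left")
  gR <- mirror_geometry(one_side("right"))
  structure(list(left = gL, right = gR,
                 truth = list(size_mult = size_mult, region = "none")),
            class = "wing_pair")
}

side_to_geometry <- function(sr, side, detail) {
  junct <- data.frame(id = sr$junction_ids,
                      x = sr$nodes[sr$junction_ids, 1],
                      y = sr$nodes[sr$junction_ids, 2],
                      degree = sr$degree[sr$junction_ids])
  cells <- if (detail == "geometry") sr$cells else list()
  g <- new_wing_geometry(side, "front", sr$outline, cells, junct)
  g$n_cells_truth <- sr$n_cells
  g
}

translate_geometry <- function(g, offset) {
  if (all(offset == 0)) return(g)
  g$outline <- sweep(g$outline, 2, -offset)
  g$cells <- lapply(g$cells, function(cl) {
    cl$vertices <- sweep(cl$vertices, 2, -offset); cl
  })
  g$junctions$x <- g$junctions$x + offset[1]
  g$junctions$y <- g$junctions$y + offset[2]
  if (!is.null(g$landmarks)) g$landmarks <- sweep(g$landmarks, 2, -offset)
  g
}

#' Generate a stressor-structured cohort of synthetic individuals
#'
#' Draws a cohort according to a factorial (or dose) design: each individual
#' carries its factor levels, sex, body-weight and emergence responses, and a
#' wing pair whose generator parameters are scaled by the configured
#' `effect_map` multipliers.
#'
#' @param config A [synthetic_config()].
#' @param design Either `NULL` (one unstructured group of
#'   `config$n_individuals`), or a data frame of numeric design columns
#'   (0/1 indicators or doses). A column `n` gives the number of individuals
#'   per design row; otherwise each row is one individual.
#' @param detail `"geometry"` (full wing pairs, asymmetry analysable) or
#'   `"counts"` (fast path: size and count responses only).
#' @param sex_balanced Alternate f/m within each design cell when `TRUE`.
#'
#' @return A list of class `wing_cohort`: `cohort` (one row per individual:
#'   covariates, body responses and — in counts detail — wing size/count
#'   responses in mm and mm^2), `pairs` (list of `wing_pair`, geometry detail
#'   only), `config`, `design`.
#' @examples
#' cfg <- synthetic_config(cells_target = 40, seed = 3)
#' co <- generate_cohort(cfg, data.frame(bti = c(0, 1), n = 2), detail = "counts")
#' co$cohort
#' @export
generate_cohort <- function(config, design = NULL,
                            detail = c("geometry", "counts", "sizes"),
                            sex_balanced = TRUE) {
  validate_synthetic_config(config)
  detail <- match.arg(detail)
  if (is.null(design)) design <- data.frame(n = config$n_individuals)
  stopifnot(is.data.frame(design))
  if (!nrow(design)) stop("empty design")

  if ("n" %in% names(design)) {
    rows <- rep(seq_len(nrow(design)), times = design$n)
    fac <- design[rows, setdiff(names(design), "n"), drop = FALSE]
  } else {
    fac <- design
  }
  n <- nrow(fac)
  fac_names <- names(fac)
  for (f in fac_names) stopifnot(is.numeric(fac[[f]]))
  # dose normalization for continuous factors
  fmax <- vapply(fac_names, function(f) max(abs(fac[[f]]), 1e-300), numeric(1))

  base_cols <- c("individual", "sex", fac_names, "wet_weight_mg",
                 "wet_weight_gain_mg", "days_to_emergence")
  count_cols <- c("wing_area", "wing_perimeter", "wing_length", "wing_width",
                  "n_cells", "n_junctions", "wing_load")
  if (n == 0) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(base_cols) +
                                          length(count_cols)),
                                    c(base_cols, count_cols)))
    empty$sex <- character(0)
    return(structure(list(cohort = empty, pairs = list(), config = config,
                          design = design), class = "wing_cohort"))
  }

  key <- if (length(fac_names)) apply(fac, 1, paste, collapse = "/") else rep("all", n)
  if (sex_balanced) {
    sex <- character(n)
    for (ix in split(seq_len(n), key)) sex[ix] <- rep(c("f", "m"), length.out = length(ix))
  } else {
    sex <- with_seed(ind_seed(config$seed, 0, 99), sample(c("f", "m"), n, TRUE))
  }

  pairs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    # treatment multipliers
    for (f in fac_names) {
      em <- config$effect_map[[f]]
      if (is.null(em)) next
      x <- fac[[f]][i] / fmax[[f]]
      for (p in names(em)) cfg_i[[p]] <- cfg_i[[p]] * em[[p]]^x
    }
    if (sex[i] == "m") {
      cfg_i$outline_length_mm <- cfg_i$outline_length_mm * config$sex_effect
      cfg_i$wet_weight_mg <- cfg_i$wet_weight_mg * config$sex_effect
    }
    body <- with_seed(ind_seed(config$seed, i, 500), list(
      ww = rlnorm(1, log(cfg_i$wet_weight_mg) - cfg_i$wet_weight_cv^2 / 2,
                  cfg_i$wet_weight_cv),
      gain = rlnorm(1, log(cfg_i$wet_weight_gain_mg) - 0.02, 0.2),
      days = rpois(1, cfg_i$days_to_emergence_mean)
    ))
    pair <- generate_wing_pair(cfg_i, ind_seed(config$seed, i, 0),
                               detail = detail)
    row <- data.frame(individual = i, sex = sex[i], fac[i, , drop = FALSE],
                      wet_weight_mg = body$ww, wet_weight_gain_mg = body$gain,
                      days_to_emergence = body$days, row.names = NULL)
    if (detail %in% c("counts", "sizes")) {
      sz <- pair_size_variables(pair)
      row <- cbind(row, sz)
      row$wing_load <- body$ww / sz$wing_area
    } else {
      pairs[[i]] <- pair
    }
    rows[[i]] <- row
  }
  cohort <- do.call(rbind, rows)
  structure(list(cohort = cohort, pairs = if (detail == "geometry") pairs else list(),
                 config = config, design = design),
            class = "wing_cohort")
}

# Pair-mean wing size and count variables (mm / mm^2) from outlines only.
pair_size_variables <- function(pair) {
  szL <- outline_size(pair$left$outline)
  szR <- outline_size(pair$right$outline)
  data.frame(
    wing_area = (szL["area"] + szR["area"]) / 2 / 1e6,
    wing_perimeter = (szL["perimeter"] + szR["perimeter"]) / 2 / 1e3,
    wing_length = (szL["length"] + szR["length"]) / 2 / 1e3,
    wing_width = (szL["width"] + szR["width"]) / 2 / 1e3,
    n_cells = (pair$left$n_cells_truth + pair$right$n_cells_truth) / 2,
    n_junctions = if (nrow(pair$left$junctions) || nrow(pair$right$junctions))
      (nrow(pair$left$junctions) + nrow(pair$right$junctions)) / 2 else NA_real_,
    row.names = NULL
  )
}

outline_size <- function(outline) {
  ext <- principal_extents(outline)
  c(area = poly_area(outline), perimeter = poly_perimeter(outline),
    length = ext[["length"]], width = ext[["width"]])
}
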