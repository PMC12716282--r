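# End-to-end orchestration: simulate a dataset to disk, analyze a cohort
# (segmentation-free geometry path), build spatial maps, with reproducible
# run manifests. Per-individual failures are isolated and logged; a run
# aborts only when more than half of the individuals fail.

#' Simulate a wing dataset to disk
#'
#' Generates a cohort and writes every artifact as plain text: the cohort
#' table and ground truth as CSV, wing geometries as JSON polygon files,
#' landmarks as CSV, the configuration and a run manifest (with file
#' checksums) as JSON; optionally rendered PNG images.
#'
#' @param config A [synthetic_config()].
#' @param design Design data frame (see [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param write_images Also render PNGs (slower, off by default).
#' @param scale_um_per_px Pixel size for rendered images.
#' @return The `wing_cohort`, invisibly, with attribute `dir`.
#' @export
cmd_simulate <- function(config, design = NULL, dir, write_images = FALSE,
                         scale_um_per_px = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(config, design, detail = "geometry")
  write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)

  truth_rows <- lapply(seq_along(sim$pairs), function(i) {
    tr <- sim$pairs[[i]]$truth
    data.frame(individual = i, region = tr$region, size_mult = tr$size_mult,
               n_matched_cells = length(tr$cell_ids),
               n_matched_junctions = length(tr$junction_ids),
               merged_left = length(tr$merged_left) > 0,
               merged_right = length(tr$merged_right) > 0)
  })
  write.csv(do.call(rbind, truth_rows), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)

  for (i in seq_along(sim$pairs)) {
    for (sd_ in c("left", "right")) {
      g <- sim$pairs[[i]][[sd_]]
      write_wing_geometry(g, file.path(dir, sprintf("wing_%03d_%s.json", i,
                                                    substr(sd_, 1, 1))))
      if (write_images) {
        img <- render_wing_image(g, scale_um_per_px)
        write_wing_png(img, file.path(dir, sprintf("wing_%03d_%s.png", i,
                                                   substr(sd_, 1, 1))))
      }
    }
  }
  lmt <- landmark_table(sim$pairs, sex = sim$cohort$sex)
  write.csv(data.frame(id = lmt$individual, side = lmt$side, sex = lmt$sex,
                       lm_index = lmt$lm, x = lmt$x, y = lmt$y),
            file.path(dir, "landmarks.csv"), row.names = FALSE)

  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(dir, list(command = "simulate", seed = config$seed,
                           n_individuals = nrow(sim$cohort)))
  attr(sim, "dir") <- dir
  invisible(sim)
}

write_manifest <- function(dir, info) {
  files <- setdiff(list.files(dir), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  jsonlite::write_json(
    c(info, list(package_version = as.character(utils::packageVersion("wingfa")),
                 files = as.list(sums))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

load_simulated_dataset <- function(dir) {
  cohort <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  n <- nrow(cohort)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    lf <- file.path(dir, sprintf("wing_%03d_l.json", i))
    rf <- file.path(dir, sprintf("wing_%03d_r.json", i))
    pairs[[i]] <- tryCatch(
      structure(list(left = read_wing_geometry(lf),
                     right = read_wing_geometry(rf), truth = NULL),
                class = "wing_pair"),
      error = function(e) e)
  }
  cfg_file <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_file))
    jsonlite::read_json(cfg_file, simplifyVector = TRUE) else NULL
  list(cohort = cohort, pairs = pairs, config = config)
}

#' Analyze a cohort of wing pairs
#'
#' Runs the geometry pipeline per individual — alignment, bidirectional
#' sister matching, the asymmetry record, the landmark FA score — merges the
#' responses into the cohort table, and fits the GLM layer. Failing
#' individuals are skipped and logged; more than 50% failures abort the run.
#'
#' @param sim A `wing_cohort` (geometry detail), or a directory written by
#'   [cmd_simulate()].
#' @param mode `"insecticide"` or `"mesocosm"` (see [run_full_analysis()]).
#' @param gate_frac,n_outline_points,outline_distance_points,max_angle,n_coarse
#'   Passed to [pair_asymmetry()].
#' @param run_glms Set `FALSE` to skip the GLM layer (records only).
#' @return A list of class `cohort_analysis`: `records` (cohort table with
#'   all asymmetry responses), `analysis` (a `stress_analysis` or `NULL`),
#'   `details` (per-individual `"full"` results for spatial mapping),
#'   `failures` (individual indices with error messages).
#' @export
analyze_cohort <- function(sim, mode = c("mesocosm", "insecticide"),
                           gate_frac = 0.25, n_outline_points = 200L,
                           outline_distance_points = NULL,
                           max_angle = pi / 4, n_coarse = 41L,
                           run_glms = TRUE) {
  if (is.null(outline_distance_points))
    outline_distance_points <- max(200L, n_outline_points)
  mode <- match.arg(mode)
  if (is.character(sim)) sim <- load_simulated_dataset(sim)
  cohort <- sim$cohort
  pairs <- sim$pairs
  n <- nrow(cohort)
  stopifnot(n == length(pairs))

  details <- vector("list", n)
  recs <- vector("list", n)
  failures <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      p <- pairs[[i]]
      if (inherits(p, "error") || inherits(p, "condition")) stop(conditionMessage(p))
      pair_asymmetry(p$left, p$right, gate_frac = gate_frac,
                     n_outline_points = n_outline_points,
                     outline_distance_points = outline_distance_points,
                     max_angle = max_angle, n_coarse = n_coarse,
                     keep = "full")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(individual = i,
                                               message = conditionMessage(res))
      next
    }
    details[[i]] <- res
    recs[[i]] <- cbind(individual = cohort$individual[i], res$record)
  }
  if (length(failures) > n / 2)
    stop("more than 50% of individuals failed analysis (",
         length(failures), "/", n, ")")
  if (length(failures))
    message(length(failures), " individual(s) skipped; run continued")

  records <- merge(cohort, do.call(rbind, recs), by = "individual")

  # landmark FA scores (per-sex Procrustes fits, pooled scores)
  ok_pairs <- which(!vapply(details, is.null, logical(1)))
  has_lm <- length(ok_pairs) > 0 &&
    all(vapply(ok_pairs, function(i) !is.null(pairs[[i]]$left$landmarks),
               logical(1)))
  if (has_lm) {
    lmt <- landmark_table(pairs[ok_pairs], sex = cohort$sex[ok_pairs])
    lmt$individual <- cohort$individual[ok_pairs][lmt$individual]
    fa <- tryCatch(fa_scores(lmt), error = function(e) NULL)
    if (!is.null(fa))
      records <- merge(records, fa[, c("individual", "fa_score")],
                       by = "individual", all.x = TRUE)
  }
  if (all(c("wet_weight_mg", "wing_area") %in% names(records)))
    records$wing_load <- wing_load(records$wet_weight_mg, records$wing_area)

  analysis <- NULL
  if (run_glms) analysis <- run_full_analysis(records, mode)
  structure(list(records = records, analysis = analysis, details = details,
                 failures = failures),
            class = "cohort_analysis")
}

#' Analyze a dataset directory and write the results bundle
#'
#' @param input Directory from [cmd_simulate()] or an in-memory
#'   `wing_cohort`.
#' @param mode Analysis mode (see [run_full_analysis()]).
#' @param output_dir Where to write `pair_asymmetry.csv`,
#'   `glm_coefficients.csv`, `lr_tests.csv`, `percentage_changes.csv`,
#'   `diagnostics.csv` and the manifest; `NULL` for in-memory only.
#' @param ... Passed to [analyze_cohort()].
#' @return The `cohort_analysis`, invisibly.
#' @export
cmd_analyze <- function(input, mode = c("mesocosm", "insecticide"),
                        output_dir = NULL, ...) {
  mode <- match.arg(mode)
  ca <- analyze_cohort(input, mode = mode, ...)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(ca$records, file.path(output_dir, "pair_asymmetry.csv"),
              row.names = FALSE)
    an <- ca$analysis
    if (!is.null(an)) {
      write.csv(an$coefficients, file.path(output_dir, "glm_coefficients.csv"),
                row.names = FALSE)
      if (!is.null(an$lr_tests))
        write.csv(an$lr_tests, file.path(output_dir, "lr_tests.csv"),
                  row.names = FALSE)
      if (!is.null(an$pct_changes))
        write.csv(an$pct_changes, file.path(output_dir, "percentage_changes.csv"),
                  row.names = FALSE)
      write.csv(an$diagnostics, file.path(output_dir, "diagnostics.csv"),
                row.names = FALSE)
    }
    write_manifest(output_dir, list(command = "analyze", mode = mode,
                                    n_failures = length(ca$failures)))
  }
  invisible(ca)
}

#' Build spatial asymmetry maps for groups of wings
#'
#' Computes per-cell asymmetry values for every analyzable pair, transforms
#' them into the common frame (upper-edge rotation + center-of-gravity
#' translation of each pair's aligned left wing), grids each group on a
#' shared 300 x 300 extent, and writes/returns treatment-minus-control
#' difference maps. Groups with fewer than 3 wings are skipped with a
#' warning. The pooled 5%/95% trim is applied for the circularity and width
#' traits.
#'
#' @param input A `cohort_analysis` from [analyze_cohort()], a
#'   `wing_cohort`, or a simulated-dataset directory.
#' @param trait Trait to map (see [per_cell_asymmetry()]).
#' @param group_col Cohort column defining the groups.
#' @param control Group label of the control (baseline) group.
#' @param output_dir Optional: writes `grid_<group>.txt/.json`, difference
#'   maps and PNG heatmaps.
#' @param grid_n Grid resolution.
#' @param blur_sigma Gaussian blur sigma (grid cells) for difference maps.
#' @param trim `NULL` = trait default (trim for circularity/width).
#' @return A list: `grids` (per group), `differences` (per non-control
#'   group), invisibly when writing.
#' @export
cmd_spatial <- function(input, trait = "centroid", group_col, control = NULL,
                        output_dir = NULL, grid_n = 300L, blur_sigma = 10,
                        trim = NULL) {
  ca <- if (inherits(input, "cohort_analysis")) input
  else analyze_cohort(input, run_glms = FALSE)
  if (is.null(trim)) trim <- trait %in% c("circularity", "width")
  cohort <- ca$records
  stopifnot(group_col %in% names(cohort))

  ok <- which(!vapply(ca$details, is.null, logical(1)))
  pts <- list(); grp <- character(0)
  for (i in ok) {
    pa <- ca$details[[i]]
    p <- per_cell_asymmetry(pa, trait)
    if (!nrow(p)) next
    tf <- superimpose_common_frame(list(pa$aligned$left))[[1]]
    pts[[length(pts) + 1]] <- apply_frame_transform(p, tf)
    ind <- if ("individual" %in% names(cohort)) cohort$individual == i else i
    grp <- c(grp, as.character(cohort[[group_col]][which(ind)[1]]))
  }
  groups <- split(pts, grp)
  sizes <- vapply(groups, length, integer(1))
  small <- names(groups)[sizes < 3]
  if (length(small)) {
    warning("group(s) with fewer than 3 wings skipped: ",
            paste(small, collapse = ", "))
    groups <- groups[sizes >= 3]
  }
  if (!length(groups)) stop("no group has enough wings for a grid")

  all_pts <- do.call(rbind, unlist(groups, recursive = FALSE))
  pad <- 0.02
  xr <- range(all_pts$x); yr <- range(all_pts$y)
  extent <- list(xlim = xr + c(-1, 1) * pad * diff(xr),
                 ylim = yr + c(-1, 1) * pad * diff(yr))

  grids <- lapply(names(groups), function(g)
    build_group_grid(groups[[g]], trait = trait, group = g, trim = trim,
                     grid_n = grid_n, extent = extent))
  names(grids) <- names(groups)

  if (is.null(control)) control <- names(grids)[1]
  stopifnot(control %in% names(grids))
  diffs <- lapply(setdiff(names(grids), control), function(g)
    difference_map(grids[[g]], grids[[control]], blur_sigma = blur_sigma))
  names(diffs) <- setdiff(names(grids), control)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in names(grids)) {
      write_grid(grids[[g]], file.path(output_dir, paste0("grid_", g)))
      png(file.path(output_dir, paste0("grid_", g, ".png")), 700, 400)
      plot(grids[[g]]); dev.off()
    }
    for (g in names(diffs)) {
      write_grid(diffs[[g]], file.path(output_dir, paste0("diff_", g)))
      png(file.path(output_dir, paste0("diff_", g, ".png")), 700, 400)
      plot(diffs[[g]]); dev.off()
    }
    write_manifest(output_dir, list(command = "spatial", trait = trait,
                                    group_col = group_col, control = control))
  }
  out <- list(grids = grids, differences = diffs)
  if (is.null(output_dir)) out else invisible(out)
}
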