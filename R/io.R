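# Plain-text readers and writers: wing geometries as JSON polygon files,
# landmark files (TPS and a CSV dialect), asymmetry grids as matrix + JSON
# sidecar.

#' Write a wing geometry to a JSON polygon file
#'
#' @param wing A `wing_geometry`.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_wing_geometry <- function(wing, path) {
  obj <- list(
    side = wing$side, wing_type = wing$wing_type,
    scale_um_per_px = wing$scale_um_per_px,
    outline = unname(apply(wing$outline, 1, as.numeric, simplify = FALSE)),
    cells = lapply(wing$cells, function(cl) list(
      id = cl$id, set_label = cl$set_label,
      vertices = unname(apply(cl$vertices, 1, as.numeric, simplify = FALSE)))),
    junctions = wing$junctions,
    landmarks = if (is.null(wing$landmarks)) NULL else
      unname(apply(wing$landmarks, 1, as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a wing geometry from a JSON polygon file
#'
#' @param path Path written by [write_wing_geometry()].
#' @return A `wing_geometry`.
#' @export
read_wing_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_poly <- function(x) {
    m <- if (is.list(x)) do.call(rbind, x) else x
    matrix(as.numeric(m), ncol = 2)
  }
  cells <- lapply(seq_len(if (is.data.frame(obj$cells)) nrow(obj$cells)
                          else length(obj$cells)), function(i) {
    cl <- if (is.data.frame(obj$cells)) obj$cells[i, ] else obj$cells[[i]]
    list(id = cl$id[[1]],
         set_label = if (is.null(cl$set_label[[1]])) NA_integer_ else cl$set_label[[1]],
         vertices = as_poly(if (is.data.frame(obj$cells)) cl$vertices[[1]] else cl$vertices))
  })
  junct <- as.data.frame(obj$junctions)
  if (!nrow(junct)) junct <- data.frame(id = integer(0), x = numeric(0),
                                        y = numeric(0), degree = integer(0))
  new_wing_geometry(obj$side, obj$wing_type, as_poly(obj$outline), cells, junct,
                    landmarks = if (is.null(obj$landmarks)) NULL else as_poly(obj$landmarks),
                    scale_um_per_px = if (is.null(obj$scale_um_per_px)) NA_real_
                    else obj$scale_um_per_px)
}

#' Read landmarks from a TPS file
#'
#' Minimal TPS dialect: `LM=k` followed by k `x y` lines, then `ID=...`
#' (and optional `SCALE=` applied multiplicatively). Specimen ids of the
#' form `<individual>_<side>` are split into the id/side columns used by
#' [fa_scores()].
#'
#' @param path TPS file path.
#' @return Long data frame `individual`, `side`, `lm`, `x`, `y`.
#' @export
read_landmarks_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list(); i <- 1
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE))
      stop("malformed TPS file: expected LM= at line ", i)
    k <- as.integer(sub("^LM=", "", lines[i], ignore.case = TRUE))
    coords <- do.call(rbind, lapply(lines[(i + 1):(i + k)], function(l)
      as.numeric(strsplit(l, "\\s+")[[1]])))
    i <- i + k + 1
    id <- NA_character_; scale <- 1
    while (i <= length(lines) && !grepl("^LM=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE))
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      if (grepl("^SCALE=", lines[i], ignore.case = TRUE))
        scale <- as.numeric(sub("^SCALE=", "", lines[i], ignore.case = TRUE))
      i <- i + 1
    }
    side <- if (grepl("_(left|right)$", id, ignore.case = TRUE))
      tolower(sub(".*_", "", id)) else NA_character_
    ind <- sub("_(left|right)$", "", id, ignore.case = TRUE)
    out[[length(out) + 1]] <- data.frame(
      individual = ind, side = side, lm = seq_len(k),
      x = coords[, 1] * scale, y = coords[, 2] * scale)
  }
  do.call(rbind, out)
}

#' Write landmarks to a TPS file
#'
#' @param landmarks Long data frame `individual`, `side`, `lm`, `x`, `y`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_tps <- function(landmarks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  key <- interaction(landmarks$individual, landmarks$side, drop = TRUE)
  for (s in split(landmarks, key)) {
    s <- s[order(s$lm), ]
    writeLines(sprintf("LM=%d", nrow(s)), con)
    writeLines(sprintf("%.10g %.10g", s$x, s$y), con)
    writeLines(sprintf("ID=%s_%s", s$individual[1], s$side[1]), con)
  }
  invisible(path)
}

#' Read landmarks from the CSV dialect
#'
#' Columns `id`, `side`, `lm_index`, `x`, `y` (a `sex` column is carried
#' through when present).
#'
#' @param path CSV file path.
#' @return Long data frame with [fa_scores()] column names.
#' @export
read_landmarks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "side", "lm_index", "x", "y") %in% names(df)))
  out <- data.frame(individual = df$id, side = tolower(df$side),
                    lm = df$lm_index, x = df$x, y = df$y)
  if ("sex" %in% names(df)) out$sex <- df$sex
  out
}

#' Write an asymmetry grid as plain-text matrix plus JSON sidecar
#'
#' @param grid An `asymmetry_grid`.
#' @param path_prefix Files `<prefix>.txt` (matrix, NA = missing) and
#'   `<prefix>.json` (extent/trait/group metadata) are written.
#' @return The two paths, invisibly.
#' @export
write_grid <- function(grid, path_prefix) {
  txt <- paste0(path_prefix, ".txt")
  js <- paste0(path_prefix, ".json")
  write.table(grid$values, txt, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(xlim = grid$xlim, ylim = grid$ylim,
                            trait = grid$trait, group = grid$group,
                            n_wings = grid$n_wings, dim = dim(grid$values)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(txt, js))
}

#' Read an asymmetry grid written by [write_grid()]
#'
#' @param path_prefix Prefix used at write time.
#' @return An `asymmetry_grid`.
#' @export
read_grid <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(read.table(paste0(path_prefix, ".txt")))
  dimnames(vals) <- NULL
  structure(list(values = vals,
                 x = seq(meta$xlim[1], meta$xlim[2], length.out = ncol(vals)),
                 y = seq(meta$ylim[1], meta$ylim[2], length.out = nrow(vals)),
                 xlim = meta$xlim, ylim = meta$ylim, trait = meta$trait,
                 group = meta$group, n_wings = meta$n_wings),
            class = "asymmetry_grid")
}
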