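# 3D water-phantom dose grids and 2D dose planes.
#
# Coordinate convention (used by every writer): right-handed, x/y lateral at
# the isocenter plane, z = water depth with the phantom surface at z = 0 and
# the surface on the isocenter plane. Grid values live at voxel centers;
# voxel ownership is half-open ([c - s/2, c + s/2) along each axis).

#' Create an empty 3D dose grid
#'
#' @param origin_mm Numeric length 3: coordinate of the first voxel center
#'   (x, y, z) in mm.
#' @param spacing_mm Isotropic voxel spacing (mm), positive.
#' @param shape Integer length 3: number of voxels (nx, ny, nz).
#' @param values Optional array of doses (Gy or Gy/proton), dimension `shape`.
#' @return An object of class `dcpt_dose_grid`.
#' @export
dose_grid <- function(origin_mm, spacing_mm = 1, shape, values = NULL) {
  stopifnot(length(origin_mm) == 3, length(shape) == 3, spacing_mm > 0)
  shape <- as.integer(shape)
  if (is.null(values)) values <- array(0, dim = shape)
  stopifnot(all(dim(values) == shape))
  structure(
    list(origin_mm = as.numeric(origin_mm), spacing_mm = spacing_mm,
         shape = shape, values = values),
    class = "dcpt_dose_grid"
  )
}

#' Voxel-center coordinates of a dose grid
#'
#' @param grid A [dose_grid()].
#' @return List with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_coords <- function(grid) {
  list(
    x = grid$origin_mm[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing_mm,
    y = grid$origin_mm[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing_mm,
    z = grid$origin_mm[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing_mm
  )
}

#' @export
print.dcpt_dose_grid <- function(x, ...) {
  cat(sprintf("<dcpt_dose_grid> %d x %d x %d voxels, %g mm spacing\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing_mm))
  cat(sprintf("  origin (%g, %g, %g) mm, max %.4g\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3], max(x$values)))
  invisible(x)
}

#' Default engine grid for a plan
#'
#' 1 mm isotropic, laterally +/- 35 mm around the beam axis and in depth
#' from the surface to 25 mm beyond the distal in-water range, with voxel
#' centers at half-integer depths (surface voxel owns `[0, 1)` mm).
#'
#' @param plan A `dcpt_plan`.
#' @param model A [beam_model()].
#' @param lateral_half_mm Lateral half extent (mm).
#' @param spacing_mm Voxel spacing (mm).
#' @return A [dose_grid()].
#' @export
default_grid <- function(plan, model, lateral_half_mm = 35, spacing_mm = 1) {
  offset <- if (plan$use_range_shifter) model$rs_wet_cm else 0
  zmax <- (max(plan$layers$range_cm) - offset) * 10 + 25
  n_lat <- 2 * floor(lateral_half_mm / spacing_mm) + 1
  nz <- ceiling(zmax / spacing_mm)
  dose_grid(
    origin_mm = c(-floor(lateral_half_mm / spacing_mm) * spacing_mm,
                  -floor(lateral_half_mm / spacing_mm) * spacing_mm,
                  spacing_mm / 2),
    spacing_mm = spacing_mm,
    shape = c(n_lat, n_lat, nz)
  )
}

#' Convert a dose grid to a long tibble
#'
#' @param x A [dose_grid()].
#' @param ... Unused.
#' @return Tibble with columns `x_mm`, `y_mm`, `z_mm`, `dose`.
#' @export
as_tibble.dcpt_dose_grid <- function(x, ...) {
  co <- grid_coords(x)
  out <- tidyr::expand_grid(z_mm = co$z, y_mm = co$y, x_mm = co$x)
  out$dose <- as.vector(x$values)
  out[, c("x_mm", "y_mm", "z_mm", "dose")]
}

#' Persist a dose grid as self-describing delimited text
#'
#' Header lines (prefixed `#`) carry the origin, spacing and shape; the
#' body is one `x y z value` row per voxel in array order.
#'
#' @param grid A [dose_grid()].
#' @param path File path.
#' @return `path` (writer) or a [dose_grid()] (reader).
#' @export
write_dose_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# dcpt_dose_grid 1.0",
    sprintf("# origin_mm %.9g %.9g %.9g", grid$origin_mm[1],
            grid$origin_mm[2], grid$origin_mm[3]),
    sprintf("# spacing_mm %.9g", grid$spacing_mm),
    sprintf("# shape %d %d %d", grid$shape[1], grid$shape[2], grid$shape[3])
  ), con)
  utils::write.table(matrix(as.vector(grid$values), ncol = 1), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path, n = 4)
  if (!startsWith(lines[1], "# dcpt_dose_grid")) {
    stop("not a dcpt_dose_grid file: ", path, call. = FALSE)
  }
  origin <- as.numeric(strsplit(lines[2], " +")[[1]][3:5])
  spacing <- as.numeric(strsplit(lines[3], " +")[[1]][3])
  shape <- as.integer(strsplit(lines[4], " +")[[1]][3:5])
  vals <- utils::read.table(path, comment.char = "#")[[1]]
  dose_grid(origin, spacing, shape, array(vals, dim = shape))
}

# ---- 2D planes --------------------------------------------------------------

#' Create a 2D dose plane
#'
#' @param x_mm,y_mm Strictly increasing, uniformly spaced coordinates (mm).
#' @param values Matrix `length(x_mm)` x `length(y_mm)` of doses.
#' @return An object of class `dcpt_plane`.
#' @export
dose_plane <- function(x_mm, y_mm, values) {
  stopifnot(nrow(values) == length(x_mm), ncol(values) == length(y_mm))
  structure(list(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                 values = values),
            class = "dcpt_plane")
}

#' @export
print.dcpt_plane <- function(x, ...) {
  cat(sprintf("<dcpt_plane> %d x %d points, x [%g, %g] mm, y [%g, %g] mm\n",
              length(x$x_mm), length(x$y_mm), min(x$x_mm), max(x$x_mm),
              min(x$y_mm), max(x$y_mm)))
  invisible(x)
}

#' @export
as_tibble.dcpt_plane <- function(x, ...) {
  out <- tidyr::expand_grid(y_mm = x$y_mm, x_mm = x$x_mm)
  out$dose <- as.vector(x$values)
  out[, c("x_mm", "y_mm", "dose")]
}

#' Extract the transverse dose plane at a depth
#'
#' Linear interpolation between the two neighbouring voxel slabs.
#'
#' @param grid A [dose_grid()].
#' @param z_mm Water depth (mm); must lie inside the grid.
#' @return A [dose_plane()].
#' @export
extract_plane <- function(grid, z_mm) {
  co <- grid_coords(grid)
  if (z_mm < co$z[1] || z_mm > co$z[length(co$z)]) {
    stop("requested depth lies outside the grid", call. = FALSE)
  }
  i <- findInterval(z_mm, co$z, all.inside = TRUE)
  t <- (z_mm - co$z[i]) / (co$z[i + 1] - co$z[i])
  vals <- (1 - t) * grid$values[, , i] + t * grid$values[, , i + 1]
  dose_plane(co$x, co$y, vals)
}

#' Write / read a 2D dose plane as delimited text
#'
#' One-line header with the axis coordinates, then one row per x position.
#'
#' @param plane A [dose_plane()].
#' @param path File path.
#' @return `path` (writer) or a [dose_plane()] (reader).
#' @export
write_plane <- function(plane, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# dcpt_plane 1.0",
               paste("# y_mm", paste(format(plane$y_mm, digits = 10),
                                     collapse = " "))), con)
  utils::write.table(cbind(plane$x_mm, plane$values), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_plane
#' @export
read_plane <- function(path) {
  lines <- readLines(path, n = 2)
  if (!startsWith(lines[1], "# dcpt_plane")) {
    stop("not a dcpt_plane file: ", path, call. = FALSE)
  }
  y <- as.numeric(strsplit(lines[2], " +")[[1]][-(1:2)])
  body <- as.matrix(utils::read.table(path, comment.char = "#"))
  dose_plane(body[, 1], y, unname(body[, -1, drop = FALSE]))
}
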