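#' Rectangular observation window
#'
#' A forest dynamics plot is modelled as a rectangular observation window with
#' its origin at one corner and coordinates in metres. The default is the
#' 500 x 500 m (25 ha) layout of large permanent plots.
#'
#' @param width,height Window dimensions in metres; both must be positive.
#' @return An object of class `plot_window` with elements `width`, `height`
#'   and `area` (m^2).
#' @examples
#' w <- fdp_window()
#' w$area / 1e4   # hectares
#' @export
fdp_window <- function(width = 500, height = 500) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1,
            length(height) == 1, width > 0, height > 0)
  structure(list(width = width, height = height, area = width * height),
            class = "plot_window")
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("Observation window: %g x %g m (%.4g ha)\n",
              x$width, x$height, x$area / 1e4))
  invisible(x)
}

#' Planar point pattern in a window
#'
#' Bundles point coordinates with the observation window and, optionally, a
#' mark per point (e.g. a species code). All points must lie inside the
#' window (boundaries included).
#'
#' @param x,y Numeric coordinate vectors (metres).
#' @param window A [fdp_window()] object.
#' @param marks Optional vector of per-point marks (same length as `x`).
#' @return An object of class `point_pattern`.
#' @examples
#' pp <- point_pattern(c(10, 20), c(30, 40), fdp_window(100, 100))
#' npoints(pp)
#' @export
point_pattern <- function(x, y, window, marks = NULL) {
  stopifnot(inherits(window, "plot_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) && (anyNA(x) || anyNA(y)))
    stop("point coordinates must not contain NA")
  if (length(x) && (any(x < 0) || any(x > window$width) ||
                    any(y < 0) || any(y > window$height)))
    stop("all points must lie inside the observation window")
  if (!is.null(marks) && length(marks) != length(x))
    stop("'marks' must have one entry per point")
  structure(list(x = x, y = y, marks = marks, window = window),
            class = "point_pattern")
}

#' Number of points in a pattern
#' @param p A `point_pattern`.
#' @return Integer count.
#' @export
npoints <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  length(p$x)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Planar point pattern: %d points in %g x %g m window%s\n",
              npoints(x), x$window$width, x$window$height,
              if (is.null(x$marks)) "" else " (marked)"))
  invisible(x)
}

#' Build a point pattern from census records
#'
#' @param stems A census data frame (see [read_census()]).
#' @param window A [fdp_window()].
#' @param marks Optional column name to use as marks (e.g. `"species"`).
#' @return A `point_pattern`.
#' @export
as_point_pattern <- function(stems, window, marks = NULL) {
  m <- if (is.null(marks)) NULL else stems[[marks]]
  point_pattern(stems$x, stems$y, window, marks = m)
}

#' Quadrat grid over a window
#'
#' Tiles the window exactly into square cells. The cell index of a point is
#' `floor(coord / cellsize)`; points on the maximal boundary are assigned to
#' the last cell so that the tiling covers the closed window.
#'
#' @param window A [fdp_window()]; its sides must be integer multiples of
#'   `cellsize`.
#' @param cellsize Cell side length in metres (default 5).
#' @return An object of class `quadrat_grid` with `nx`, `ny`, `cellsize`,
#'   `window`.
#' @examples
#' g <- quadrat_grid(fdp_window())
#' c(g$nx, g$ny)   # 100 x 100 cells
#' @export
quadrat_grid <- function(window, cellsize = 5) {
  stopifnot(inherits(window, "plot_window"), cellsize > 0)
  nx <- window$width / cellsize
  ny <- window$height / cellsize
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("window dimensions must be integer multiples of the cell size")
  structure(list(nx = as.integer(round(nx)), ny = as.integer(round(ny)),
                 cellsize = cellsize, window = window),
            class = "quadrat_grid")
}

#' Cell index of points in a quadrat grid
#'
#' @param grid A [quadrat_grid()].
#' @param x,y Point coordinates.
#' @return Integer vector of 1-based cell ids, numbered column-major
#'   (`ix + nx * iy + 1` with 0-based `ix`, `iy`).
#' @export
quadrat_index <- function(grid, x, y) {
  stopifnot(inherits(grid, "quadrat_grid"))
  ix <- pmin(floor(x / grid$cellsize), grid$nx - 1)
  iy <- pmin(floor(y / grid$cellsize), grid$ny - 1)
  if (length(x) && (any(ix < 0) || any(iy < 0)))
    stop("points must have non-negative coordinates")
  as.integer(ix + grid$nx * iy + 1L)
}
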