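#' Regular latitude-longitude grid specification
#'
#' Defines a cell-edge registered lat-lon grid. Row 1 is the northernmost
#' row; columns run west to east. Fields on the grid are plain numeric
#' matrices of dimension `nlat x nlon`.
#'
#' @param resolution Cell size in degrees (identical for both axes).
#' @param lat_min,lat_max Latitude extent in degrees, within \[-90, 90\].
#' @param lon_min,lon_max Longitude extent in degrees.
#' @return An object of class `grid_spec` with fields `resolution`,
#'   `lat_min`, `lat_max`, `lon_min`, `lon_max`, `nlat`, `nlon`.
#' @examples
#' g <- grid_spec(0.5, lat_min = 0, lat_max = 2, lon_min = 0, lon_max = 2)
#' g$nlat  # 4
#' @export
grid_spec <- function(resolution, lat_min, lat_max, lon_min, lon_max) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  if (lat_min < -90 - 1e-9 || lat_max > 90 + 1e-9)
    stop("latitude bounds must lie within [-90, 90]")
  if (lat_max <= lat_min || lon_max <= lon_min)
    stop("degenerate grid: extents must be strictly positive")
  nlat <- (lat_max - lat_min) / resolution
  nlon <- (lon_max - lon_min) / resolution
  if (abs(nlat - round(nlat)) > 1e-6 || abs(nlon - round(nlon)) > 1e-6)
    stop("grid extents must be integer multiples of the resolution")
  structure(list(
    resolution = resolution,
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    nlat = as.integer(round(nlat)), nlon = as.integer(round(nlon))
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %g deg, lat [%g, %g], lon [%g, %g], %d x %d cells\n",
              x$resolution, x$lat_min, x$lat_max, x$lon_min, x$lon_max,
              x$nlat, x$nlon))
  invisible(x)
}

#' Refine a grid by an integer factor
#'
#' Produces the nested fine grid whose cells subdivide each coarse cell
#' `factor x factor`. The default factor of 6 turns a 0.5-degree grid into a
#' 5-arc-minute grid, the nesting used for fractional polygon rasterisation.
#'
#' @param grid A `grid_spec`.
#' @param factor Integer subdivision factor per axis.
#' @return A `grid_spec` with `factor^2` times as many cells.
#' @export
refine_grid <- function(grid, factor = 6L) {
  stopifnot(inherits(grid, "grid_spec"), factor >= 1)
  grid_spec(grid$resolution / factor, grid$lat_min, grid$lat_max,
            grid$lon_min, grid$lon_max)
}

#' Check that a fine grid nests exactly into a coarse grid
#' @noRd
grids_nested <- function(fine, coarse, factor = 6L) {
  same_ext <- isTRUE(all.equal(c(fine$lat_min, fine$lat_max, fine$lon_min, fine$lon_max),
                               c(coarse$lat_min, coarse$lat_max, coarse$lon_min, coarse$lon_max),
                               tolerance = 1e-9))
  same_ext && abs(coarse$resolution / fine$resolution - factor) < 1e-9
}

#' Latitude bounds of each grid row (north to south)
#' @noRd
row_lat_bounds <- function(grid) {
  upper <- grid$lat_max - (seq_len(grid$nlat) - 1L) * grid$resolution
  cbind(lower = upper - grid$resolution, upper = upper)
}

#' Cell-centre coordinates
#'
#' @param grid A `grid_spec`.
#' @return A list with `lat` (length `nlat`, north to south) and `lon`
#'   (length `nlon`, west to east) centre coordinates in degrees.
#' @export
cell_centres <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(
    lat = grid$lat_max - (seq_len(grid$nlat) - 0.5) * grid$resolution,
    lon = grid$lon_min + (seq_len(grid$nlon) - 0.5) * grid$resolution
  )
}

#' Spherical cell areas of a grid
#'
#' Area of the cell spanning latitudes \[phi1, phi2\] and a longitude width
#' of dlambda radians on a sphere of radius R is
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))`, so areas are constant within a
#' latitude row and shrink towards the poles.
#'
#' @param grid A `grid_spec`.
#' @param earth_radius Sphere radius in km (default 6371, the Earth's
#'   authalic radius to within a few km).
#' @return A `nlat x nlon` matrix of cell areas in km^2.
#' @examples
#' g <- grid_spec(10, -90, 90, -180, 180)
#' sum(cell_areas(g))  # 4 * pi * 6371^2
#' @export
cell_areas <- function(grid, earth_radius = 6371) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$nlat < 1L || grid$nlon < 1L) stop("degenerate grid: zero cells")
  b <- row_lat_bounds(grid)
  dlon <- grid$resolution * pi / 180
  row_area <- earth_radius^2 * dlon *
    (sin(b[, "upper"] * pi / 180) - sin(b[, "lower"] * pi / 180))
  matrix(row_area, nrow = grid$nlat, ncol = grid$nlon)
}

#' Block-aggregate a matrix by summation
#' @noRd
block_sum <- function(m, factor) {
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  m1 <- rowsum(m, rep(seq_len(nr), each = factor), reorder = FALSE)
  out <- t(rowsum(t(m1), rep(seq_len(nc), each = factor), reorder = FALSE))
  dimnames(out) <- NULL
  out
}

#' Upscale a fractional field from a fine to a coarse grid
#'
#' Aggregates by area: the coarse value is the area represented by the fine
#' fractions divided by the coarse cell area, so total class area is conserved
#' exactly. This mirrors upscaling land-use class areas from a 5-arc-minute
#' grid to a 0.5-degree grid by summation.
#'
#' @param fine Numeric matrix of fractions on `fine_grid`.
#' @param fine_grid,coarse_grid Nested `grid_spec`s (fine = coarse / `factor`).
#' @param factor Integer nesting factor (default 6).
#' @param earth_radius Sphere radius in km.
#' @return Matrix of fractions on the coarse grid, values in \[0, 1\].
#' @export
upscale_fractions <- function(fine, fine_grid, coarse_grid, factor = 6L,
                              earth_radius = 6371) {
  if (!grids_nested(fine_grid, coarse_grid, factor))
    stop("fine grid does not nest into coarse grid with factor ", factor)
  stopifnot(nrow(fine) == fine_grid$nlat, ncol(fine) == fine_grid$nlon)
  fine_a <- cell_areas(fine_grid, earth_radius)
  coarse_a <- cell_areas(coarse_grid, earth_radius)
  out <- block_sum(fine * fine_a, factor) / coarse_a
  # guard against floating-point overshoot just above 1
  pmin(pmax(out, 0), 1)
}

#' Nearest-neighbour regridding
#'
#' Assigns to each target cell the value of the source cell containing the
#' target cell's centre. Used to bring coarse climate-model fields onto the
#' finer observational grid before delta-method differencing.
#'
#' @param field Numeric matrix on `from_grid`.
#' @param from_grid,to_grid `grid_spec`s covering the same extent.
#' @return Numeric matrix on `to_grid`.
#' @export
regrid_nearest <- function(field, from_grid, to_grid) {
  stopifnot(nrow(field) == from_grid$nlat, ncol(field) == from_grid$nlon)
  cc <- cell_centres(to_grid)
  ri <- pmin(pmax(ceiling((from_grid$lat_max - cc$lat) / from_grid$resolution), 1L),
             from_grid$nlat)
  ci <- pmin(pmax(ceiling((cc$lon - from_grid$lon_min) / from_grid$resolution), 1L),
             from_grid$nlon)
  field[ri, ci, drop = FALSE]
}
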