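#' Point-in-polygon test with an inclusive boundary rule
#'
#' Even-odd (ray casting) test of many points against one ring. A point lying
#' exactly on a polygon edge or vertex counts as inside; this deterministic
#' tie-break matters because cell centres of regular grids frequently land on
#' the axis-aligned edges of range polygons.
#'
#' @param px,py Point coordinates (equal-length numeric vectors).
#' @param ring Two-column matrix of ring vertices (x, y); the ring is closed
#'   implicitly if the last vertex differs from the first.
#' @return Logical vector, `TRUE` for points inside or on the boundary.
#' @export
point_in_ring <- function(px, py, ring) {
  stopifnot(length(px) == length(py), ncol(ring) == 2)
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- nrow(ring)
  if (xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1L  # drop duplicate closure
  if (n < 3L) stop("invalid ring: fewer than 3 distinct vertices")
  inside <- logical(length(px))
  onedge <- logical(length(px))
  eps <- 1e-12 * max(1, max(abs(xs)), max(abs(ys)))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # on-segment: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on <- abs(cross) <= eps * max(1, seg_len) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | on
    # strict crossing count for the horizontal ray towards +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | onedge
}

#' Validate a polygon ring
#'
#' Rejects rings with fewer than three distinct vertices, non-finite
#' coordinates, or self-intersections (proper crossings between
#' non-adjacent edges).
#' @noRd
validate_ring <- function(ring) {
  if (!is.matrix(ring) || ncol(ring) != 2 || !all(is.finite(ring)))
    stop("invalid ring: need a finite two-column coordinate matrix")
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- nrow(ring)
  if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1L }
  if (n < 3L) stop("invalid ring: fewer than 3 distinct vertices")
  # proper-intersection check between non-adjacent edges; rings are small
  seg <- cbind(xs, ys, xs[c(2:n, 1)], ys[c(2:n, 1)])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2L)) {
    for (k in (i + 2L):n) {
      if (i == 1L && k == n) next  # adjacent through closure
      o1 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[k, 1], seg[k, 2])
      o2 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[k, 3], seg[k, 4])
      o3 <- orient(seg[k, 1], seg[k, 2], seg[k, 3], seg[k, 4], seg[i, 1], seg[i, 2])
      o4 <- orient(seg[k, 1], seg[k, 2], seg[k, 3], seg[k, 4], seg[i, 3], seg[i, 4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        stop("invalid ring: self-intersecting")
    }
  }
  invisible(TRUE)
}

#' Shift ring longitudes into the grid frame
#'
#' Normalises by whole turns of 360 degrees so the ring's longitude midpoint
#' falls inside the grid's longitude extent. Rings crossing the antimeridian
#' must be pre-split by the caller; a single ring is shifted rigidly.
#' @noRd
normalise_ring_lon <- function(ring, grid) {
  mid <- mean(range(ring[, 1]))
  shift <- 0
  while (mid + shift < grid$lon_min) shift <- shift + 360
  while (mid + shift > grid$lon_max) shift <- shift - 360
  ring[, 1] <- ring[, 1] + shift
  ring
}

#' Fractional coverage of a polygon on a coarse grid
#'
#' Rasterises a polygon (one or more rings, even-odd rule so interior rings
#' act as holes) to the fine grid by the centre-containment rule, then
#' expresses coverage of each coarse cell as the proportion of its fine
#' subcells whose centres fall inside. With the default 6x6 nesting the
#' coarse values are multiples of 1/36. `weighting = "area"` instead weights
#' each flagged subcell by its spherical area.
#'
#' @param rings A single two-column matrix (lon, lat) or a list of such ring
#'   matrices.
#' @param fine_grid,coarse_grid Nested `grid_spec`s.
#' @param factor Nesting factor (default 6).
#' @param weighting `"count"` (default; flagged / factor^2) or `"area"`.
#' @return Matrix of coverage fractions on the coarse grid.
#' @export
polygon_coverage <- function(rings, fine_grid, coarse_grid, factor = 6L,
                             weighting = c("count", "area")) {
  weighting <- match.arg(weighting)
  if (!grids_nested(fine_grid, coarse_grid, factor))
    stop("fine grid does not nest into coarse grid with factor ", factor)
  if (is.matrix(rings)) rings <- list(rings)
  flags <- fine_flags(rings, fine_grid)
  if (weighting == "count") {
    block_sum(flags, factor) / factor^2
  } else {
    upscale_fractions(flags, fine_grid, coarse_grid, factor)
  }
}

#' 0/1 matrix of fine cells whose centres lie inside the polygon
#' @noRd
fine_flags <- function(rings, fine_grid) {
  flags <- matrix(0, fine_grid$nlat, fine_grid$nlon)
  if (length(rings) == 0) return(flags)
  for (r in rings) validate_ring(r)
  rings <- lapply(rings, normalise_ring_lon, grid = fine_grid)
  cc <- cell_centres(fine_grid)
  # restrict the point test to the polygon's bounding box
  bb <- do.call(rbind, rings)
  rows <- which(cc$lat >= min(bb[, 2]) - fine_grid$resolution &
                cc$lat <= max(bb[, 2]) + fine_grid$resolution)
  cols <- which(cc$lon >= min(bb[, 1]) - fine_grid$resolution &
                cc$lon <= max(bb[, 1]) + fine_grid$resolution)
  if (!length(rows) || !length(cols)) return(flags)
  px <- rep(cc$lon[cols], each = length(rows))
  py <- rep(cc$lat[rows], times = length(cols))
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  for (r in rings) {
    hit <- point_in_ring(px, py, r)
    # even-odd across rings, but boundary stays inside
    strict <- point_in_ring_strict(px, py, r)
    inside <- xor(inside, strict)
    onedge <- onedge | (hit & !strict)
  }
  flags[rows, cols] <- as.numeric(inside | onedge)
  flags
}

#' Even-odd test without the boundary override (internal helper for
#' multi-ring even-odd combination).
#' @noRd
point_in_ring_strict <- function(px, py, ring) {
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- nrow(ring)
  if (xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1L
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Read polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon / MultiPolygon geometries. Each
#' feature becomes a list of rings (two-column lon/lat matrices); the
#' feature's `id` property (or its index) names the element.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list; each element is a list of ring matrices.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- if (!is.null(f$geometry)) f$geometry else f
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, coords_to_matrix),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, coords_to_matrix)), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type)
    )
    id <- if (!is.null(f$properties$id)) as.character(f$properties$id) else as.character(i)
    out[[id]] <- rings
  }
  out
}

#' @noRd
coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}
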