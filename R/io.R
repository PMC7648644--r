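#' Write a gridded field to long-format CSV
#'
#' Plain-text contract for gridded fractions and biome codes: one row per
#' cell with columns `lat`, `lon` (cell centres) and `value`, preceded by a
#' single comment line carrying the grid spec, e.g.
#' `# grid resolution=0.5 lat=[-30,30] lon=[0,30]`.
#'
#' @param field Numeric matrix on `grid`.
#' @param grid A `grid_spec`.
#' @param path Output path.
#' @export
write_field_csv <- function(field, grid, path) {
  stopifnot(nrow(field) == grid$nlat, ncol(field) == grid$nlon)
  cc <- cell_centres(grid)
  df <- data.frame(lat = rep(cc$lat, times = grid$nlon),
                   lon = rep(cc$lon, each = grid$nlat),
                   value = as.vector(field))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid resolution=%.10g lat=[%.10g,%.10g] lon=[%.10g,%.10g]",
                     grid$resolution, grid$lat_min, grid$lat_max,
                     grid$lon_min, grid$lon_max), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a gridded field from long-format CSV
#'
#' @param path Path written by [write_field_csv()].
#' @return List with `field` (matrix) and `grid` (`grid_spec`).
#' @export
read_field_csv <- function(path) {
  header <- readLines(path, n = 1)
  nums <- as.numeric(regmatches(header, gregexpr("-?[0-9.]+", header))[[1]])
  grid <- grid_spec(nums[1], lat_min = nums[2], lat_max = nums[3],
                    lon_min = nums[4], lon_max = nums[5])
  df <- utils::read.csv(path, comment.char = "#")
  cc <- cell_centres(grid)
  ri <- match(round(df$lat, 6), round(cc$lat, 6))
  ci <- match(round(df$lon, 6), round(cc$lon, 6))
  if (anyNA(ri) || anyNA(ci)) stop("cell coordinates do not match the grid header")
  field <- matrix(NA_real_, grid$nlat, grid$nlon)
  field[cbind(ri, ci)] <- df$value
  list(field = field, grid = grid)
}

#' Write polygons to GeoJSON
#'
#' Each list element becomes a Polygon feature (its rings as coordinate
#' arrays) with its name as the `id` property.
#'
#' @param polygons Named list; each element a ring matrix or list of ring
#'   matrices (lon, lat columns).
#' @param path Output path.
#' @export
write_geojson_polygons <- function(polygons, path) {
  feats <- lapply(names(polygons), function(id) {
    rings <- polygons[[id]]
    if (is.matrix(rings)) rings <- list(rings)
    coords <- lapply(rings, function(r) {
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature", properties = list(id = id),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Export a range-series table to tidy CSV
#'
#' @param ranges Data frame as produced by [run_pipeline()] (`$ranges`) or
#'   [run_future()].
#' @param path Output path.
#' @export
write_ranges_csv <- function(ranges, path) {
  utils::write.csv(ranges, path, row.names = FALSE)
}
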