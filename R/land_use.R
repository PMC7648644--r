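#' Land-use class constants
#' @noRd
LU_CLASSES <- c("cropland", "pasture", "urban")
LU_VARIANTS <- c("baseline", "lower", "upper")

#' Construct a time-indexed land-use series
#'
#' Holds per-cell cropland, pasture and urban fractions for an ordered set of
#' years, with up to three uncertainty variants. Fractions are validated to
#' \[0, 1\]; cells whose class sum exceeds 1 are rescaled proportionally to
#' sum to 1 on ingest, and the number of affected cells is recorded in the
#' `clamped_cells` attribute.
#'
#' @param grid A `grid_spec`.
#' @param years Strictly increasing integer years.
#' @param data Named list, one element per variant (`baseline`, optionally
#'   `lower`/`upper`); each element an array of dimension
#'   `c(nlat, nlon, 3, length(years))` with the third dimension named by
#'   class (`cropland`, `pasture`, `urban`).
#' @return An object of class `landuse_series`.
#' @export
landuse_series <- function(grid, years, data) {
  stopifnot(inherits(grid, "grid_spec"))
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  if (!"baseline" %in% names(data)) stop("a 'baseline' variant is required")
  clamped <- 0L
  for (v in names(data)) {
    a <- data[[v]]
    if (!identical(dim(a)[1:2], c(grid$nlat, grid$nlon)) ||
        dim(a)[3] != 3L || dim(a)[4] != length(years))
      stop("variant '", v, "': array dimensions do not match grid/classes/years")
    if (is.null(dimnames(a)[[3]])) dimnames(a)[[3]] <- LU_CLASSES
    if (!all(LU_CLASSES %in% dimnames(a)[[3]]))
      stop("all three classes (cropland, pasture, urban) must be present")
    if (any(a < -1e-9) || any(a > 1 + 1e-9))
      stop("variant '", v, "': fractions outside [0, 1]")
    a <- pmin(pmax(a, 0), 1)
    tot <- a[, , "cropland", , drop = FALSE] + a[, , "pasture", , drop = FALSE] +
      a[, , "urban", , drop = FALSE]
    over <- tot > 1 + 1e-6
    if (any(over)) {
      clamped <- clamped + sum(over)
      scale <- ifelse(tot > 1, 1 / tot, 1)
      for (k in LU_CLASSES) a[, , k, ] <- a[, , k, , drop = FALSE] * scale
    }
    data[[v]] <- a
  }
  obj <- structure(list(grid = grid, years = years, data = data),
                   class = "landuse_series", clamped_cells = clamped)
  check_variant_order(obj)
  obj
}

#' Warn (not error) if lower <= baseline <= upper is violated anywhere
#' @noRd
check_variant_order <- function(series) {
  d <- series$data
  if (all(c("lower", "upper") %in% names(d))) {
    if (any(d$lower > d$baseline + 1e-9) || any(d$baseline > d$upper + 1e-9))
      warning("variant ordering violated: expected lower <= baseline <= upper")
  }
  invisible(series)
}

#' @export
print.landuse_series <- function(x, ...) {
  cat(sprintf("landuse_series: %d years (%d-%d), variants: %s, %d x %d cells\n",
              length(x$years), min(x$years), max(x$years),
              paste(names(x$data), collapse = ", "), x$grid$nlat, x$grid$nlon))
  invisible(x)
}

#' Extract one class layer
#'
#' @param series A `landuse_series`.
#' @param class One of `"cropland"`, `"pasture"`, `"urban"`.
#' @param year A year present in the series.
#' @param variant Variant name (default `"baseline"`).
#' @return Matrix of fractions on the series grid.
#' @export
lu_layer <- function(series, class, year, variant = "baseline") {
  ti <- match(as.integer(year), series$years)
  if (is.na(ti)) stop("year ", year, " not in series")
  if (!variant %in% names(series$data)) stop("variant '", variant, "' not in series")
  m <- series$data[[variant]][, , class, ti, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' All three class layers at one time
#' @noRd
lu_classes_at <- function(series, year, variant = "baseline") {
  stats::setNames(lapply(LU_CLASSES, lu_layer, series = series, year = year,
                         variant = variant), LU_CLASSES)
}

#' Harmonise a future land-use series with a historical one
#'
#' Anchors future projections to the historical reconstruction by adding, per
#' class and cell, the historical-minus-future difference at the junction
#' year (2010) to every future time step. Results are clamped to \[0, 1\];
#' where clamping pushes a cell's class sum above 1 the classes are rescaled
#' proportionally. At the junction year the output equals the historical
#' series exactly.
#'
#' @param hist,future `landuse_series` objects on the same grid, both
#'   containing `junction_year`.
#' @param junction_year Year at which the two series are spliced (default 2010).
#' @return A `landuse_series` on the future time grid.
#' @export
harmonise_future <- function(hist, future, junction_year = 2010L) {
  for (s in list(hist, future))
    if (!junction_year %in% s$years)
      stop("junction year ", junction_year, " missing from a series")
  out <- future$data
  for (v in names(out)) {
    hv <- if (v %in% names(hist$data)) v else "baseline"
    a <- out[[v]]
    for (k in LU_CLASSES) {
      delta <- lu_layer(hist, k, junction_year, hv) -
        lu_layer(future, k, junction_year, v)
      for (ti in seq_along(future$years))
        a[, , k, ti] <- a[, , k, ti] + delta
    }
    out[[v]] <- pmin(pmax(a, 0), 1)
  }
  landuse_series(future$grid, future$years, out)
}

#' Total converted (cropland + pasture + urban) fraction per cell
#' @noRd
converted_fraction <- function(series, year, variant = "baseline") {
  cls <- lu_classes_at(series, year, variant)
  pmin(cls$cropland + cls$pasture + cls$urban, 1)
}

#' Cumulative converted area at a point in time
#'
#' Global agricultural plus urban area: the per-cell class sum (capped at 1)
#' times the spherical cell area, summed over the grid.
#'
#' @param series A `landuse_series`.
#' @param year A year present in the series.
#' @param variant Variant name.
#' @param areas Cell-area matrix from [cell_areas()].
#' @return Converted area in km^2.
#' @export
cumulative_converted_area <- function(series, year, variant = "baseline",
                                      areas = cell_areas(series$grid)) {
  sum(converted_fraction(series, year, variant) * areas)
}

#' Local time of the fastest conversion to agricultural and urban land
#'
#' For each cell, computes conversion rates between consecutive time points
#' up to `t_max` and returns the end year of the interval with the highest
#' rate; ties go to the earliest interval. Cells where no interval shows a
#' positive rate are flagged as no-conversion (`NA`).
#'
#' @param series A `landuse_series` with at least two time points <= `t_max`.
#' @param t_max Last year considered (default: last year of the series).
#' @param variant Variant name.
#' @return Integer matrix of years, `NA` where no conversion occurred.
#' @export
peak_conversion_time <- function(series, t_max = max(series$years),
                                 variant = "baseline") {
  yrs <- series$years[series$years <= t_max]
  if (length(yrs) < 2L) stop("need at least two time points <= t_max")
  conv <- vapply(yrs, function(y) converted_fraction(series, y, variant),
                 matrix(0, series$grid$nlat, series$grid$nlon))
  dt <- diff(yrs)
  nlat <- series$grid$nlat; nlon <- series$grid$nlon
  rates <- array(0, c(nlat, nlon, length(dt)))
  for (k in seq_along(dt))
    rates[, , k] <- (conv[, , k + 1] - conv[, , k]) / dt[k]
  best <- apply(rates, c(1, 2), which.max)     # earliest max by construction
  maxrate <- apply(rates, c(1, 2), max)
  out <- matrix(yrs[-1][best], nlat, nlon)
  out[maxrate <= 0] <- NA_integer_
  out
}
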