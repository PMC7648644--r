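#' Monthly climate field for one year
#'
#' Twelve monthly per-cell values of one variable. Valid ranges are enforced:
#' precipitation must be non-negative (mm/month) and percent sunshine within
#' \[0, 100\]; temperature (degrees C) is unrestricted.
#'
#' @param variable One of `"temperature"`, `"precipitation"`, `"sunshine"`.
#' @param year Calendar year.
#' @param grid A `grid_spec`.
#' @param data Array of dimension `c(nlat, nlon, 12)`.
#' @return An object of class `climate_field`.
#' @export
climate_field <- function(variable, year, grid, data) {
  variable <- match.arg(variable, c("temperature", "precipitation", "sunshine"))
  stopifnot(inherits(grid, "grid_spec"))
  if (length(dim(data)) != 3L || dim(data)[3] != 12L ||
      !identical(dim(data)[1:2], c(grid$nlat, grid$nlon)))
    stop("data must be a (nlat, nlon, 12) array of monthly values")
  if (variable == "precipitation" && any(data < 0))
    stop("precipitation must be non-negative")
  if (variable == "sunshine" && (any(data < 0) || any(data > 100)))
    stop("percent sunshine must lie within [0, 100]")
  structure(list(variable = variable, year = as.integer(year),
                 grid = grid, data = data), class = "climate_field")
}

#' Valid range for a climate variable, used when clamping after correction
#' @noRd
clamp_climate <- function(values, variable) {
  switch(variable,
    temperature = values,
    precipitation = pmax(values, 0),
    sunshine = pmin(pmax(values, 0), 100))
}

#' Delta-method bias correction and downscaling
#'
#' Adds the observed-minus-simulated difference at a reference time to the
#' simulated field at the target time:
#' `out = sim_t + (obs_ref - sim_ref)`, per cell and month. The simulated
#' fields are first regridded (nearest neighbour) to the observational grid,
#' which is what downscales the output. The additive rule is used for all
#' three variables; precipitation and sunshine are clamped to their valid
#' ranges afterwards.
#'
#' @param sim_t `climate_field` to correct (any grid covering the obs extent).
#' @param sim_ref Simulated reference `climate_field`, same grid as `sim_t`.
#' @param obs_ref Observed reference `climate_field` on the target grid.
#' @return A `climate_field` on the observational grid, same variable and
#'   year as `sim_t`.
#' @export
delta_correct <- function(sim_t, sim_ref, obs_ref) {
  vars <- c(sim_t$variable, sim_ref$variable, obs_ref$variable)
  if (length(unique(vars)) != 1L)
    stop("variable mismatch: ", paste(vars, collapse = ", "))
  if (!identical(unclass(sim_t$grid), unclass(sim_ref$grid)))
    stop("sim_t and sim_ref must share a grid")
  g <- obs_ref$grid
  slice <- function(f, m) matrix(f$data[, , m], f$grid$nlat, f$grid$nlon)
  out <- array(0, c(g$nlat, g$nlon, 12))
  for (m in 1:12) {
    sim_t_m <- regrid_nearest(slice(sim_t, m), sim_t$grid, g)
    sim_ref_m <- regrid_nearest(slice(sim_ref, m), sim_ref$grid, g)
    out[, , m] <- clamp_climate(sim_t_m + (slice(obs_ref, m) - sim_ref_m),
                                sim_t$variable)
  }
  climate_field(sim_t$variable, sim_t$year, g, out)
}

#' Average annual climate fields over a trailing window
#'
#' Per-cell, per-month arithmetic mean over all years in the closed interval
#' `[t - window_years, t]` (31 annual fields for the default 30-year window).
#' Every year in the interval must be present.
#'
#' @param series List of `climate_field`s of one variable, one per year.
#' @param t Target year.
#' @param window_years Window length in years (default 30).
#' @return A `climate_field` labelled with year `t`.
#' @export
window_average <- function(series, t, window_years = 30L) {
  yrs <- vapply(series, function(f) f$year, integer(1))
  wanted <- seq.int(t - window_years, t)
  missing_yrs <- setdiff(wanted, yrs)
  if (length(missing_yrs))
    stop("missing years in averaging window: ", paste(missing_yrs, collapse = ", "))
  sel <- series[match(wanted, yrs)]
  acc <- sel[[1]]$data
  for (f in sel[-1]) acc <- acc + f$data
  climate_field(sel[[1]]$variable, t, sel[[1]]$grid, acc / length(sel))
}
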