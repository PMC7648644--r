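#' Relative range change against the baseline potential range
#'
#' `100 * (A_actual(t) / A_potential(t0) - 1)`, in percent. A zero baseline
#' leaves the change undefined; such species are excluded from all
#' across-species statistics and get `NA`.
#'
#' @param a_actual Actual range size(s) at time t, km^2.
#' @param a_potential_t0 Baseline potential range size(s) at the reference
#'   year, km^2.
#' @return Percent change(s); `NA` where the baseline is zero.
#' @examples
#' range_change(50, 100)   # -50
#' range_change(0, 100)    # -100
#' range_change(150, 100)  # +50
#' @export
range_change <- function(a_actual, a_potential_t0) {
  out <- 100 * (a_actual / a_potential_t0 - 1)
  out[a_potential_t0 <= 0] <- NA_real_
  out
}

#' Range change attributable to biome shifts alone
#'
#' Same formula as [range_change()] but with the time-varying potential range
#' in the numerator, isolating the climate-driven component from land use.
#'
#' @param a_potential_t Potential range size(s) at time t, km^2.
#' @param a_potential_t0 Baseline potential range size(s), km^2.
#' @return Percent change(s); `NA` where the baseline is zero.
#' @export
climate_only_change <- function(a_potential_t, a_potential_t0) {
  range_change(a_potential_t, a_potential_t0)
}

#' Across-species percentile curves of range change
#'
#' Percentiles of the included species' range changes at each time point,
#' using linear interpolation between order statistics
#' (`stats::quantile` type 7). `NA` changes (excluded species) are dropped.
#'
#' @param changes Data frame with columns `year` and `delta_pct`.
#' @param percentiles Percentile levels in percent (default 10, 20, ..., 90).
#' @return Data frame with columns `year`, `percentile`, `value`.
#' @export
percentile_curves <- function(changes, percentiles = seq(10, 90, by = 10)) {
  stopifnot(all(c("year", "delta_pct") %in% names(changes)))
  ok <- changes[!is.na(changes$delta_pct), ]
  if (!nrow(ok)) stop("no included species")
  out <- do.call(rbind, lapply(split(ok, ok$year), function(d) {
    q <- stats::quantile(d$delta_pct, probs = percentiles / 100,
                         type = 7, names = FALSE)
    data.frame(year = d$year[1], percentile = percentiles, value = q)
  }))
  rownames(out) <- NULL
  out[order(out$year, out$percentile), ]
}

#' Share of species past a critical range-loss threshold
#'
#' Proportion of included species whose range change is strictly below
#' `-threshold` percent. With a grouping, returns per-group shares under two
#' normalisations: within the group (`share_within`) and relative to all
#' included species (`share_of_all`); empty groups get `NA` shares.
#'
#' @param delta_pct Numeric vector of range changes (percent; `NA` = excluded).
#' @param threshold Loss threshold in percent (default 50).
#' @param groups Optional factor/character vector of group labels
#'   (e.g. primary mega-biome), same length as `delta_pct`.
#' @return Without groups, a single proportion. With groups, a data frame
#'   with columns `group`, `n`, `n_critical`, `share_within`, `share_of_all`.
#' @export
critical_loss_fraction <- function(delta_pct, threshold = 50, groups = NULL) {
  keep <- !is.na(delta_pct)
  if (!any(keep)) stop("no included species")
  crit <- delta_pct < -threshold & keep
  if (is.null(groups)) return(sum(crit) / sum(keep))
  stopifnot(length(groups) == length(delta_pct))
  g <- factor(groups[keep])
  crit <- crit[keep]
  n <- as.vector(table(g))
  nc <- as.vector(tapply(crit, g, sum, default = 0))
  data.frame(group = levels(g), n = n, n_critical = nc,
             share_within = ifelse(n > 0, nc / n, NA_real_),
             share_of_all = nc / sum(n))
}

#' Primary mega-biome of a species
#'
#' The mega-biome (coarse biome grouping, e.g. tropical vs temperate vs
#' boreal) whose member biomes contribute the largest share of the species'
#' baseline potential range area. Ties go to the lexicographically lowest
#' mega-biome label.
#'
#' @param sp A `species_record` with nonzero baseline potential range.
#' @param biomes_t0 Baseline `biome_map`.
#' @param mega Named vector or data frame mapping biome code to mega-biome
#'   label: either `c("1" = "tropical", ...)` or a data frame with columns
#'   `biome` and `mega_biome`.
#' @param areas Cell-area matrix.
#' @return Character mega-biome label.
#' @export
primary_mega_biome <- function(sp, biomes_t0, mega, areas = cell_areas(sp$grid)) {
  if (is.data.frame(mega))
    mega <- stats::setNames(as.character(mega$mega_biome), mega$biome)
  pot <- potential_range_field(sp, biomes_t0)
  if (sum(pot * areas) <= 0) stop("zero baseline potential range: species excluded")
  contrib <- tapply(as.vector(pot * areas), as.vector(biomes_t0$codes), sum)
  contrib <- contrib[contrib > 0]
  labels <- mega[names(contrib)]
  by_mega <- tapply(as.vector(contrib), as.vector(labels), sum)
  cand <- names(by_mega)[by_mega == max(by_mega)]
  sort(cand)[1]
}

#' Median range loss against cumulative converted area
#'
#' Pairs the across-species median loss with the cumulative global converted
#' area at each time point, ordered by time, and derives marginal losses —
#' the additional percent of range lost per unit of newly converted area —
#' by successive differences.
#'
#' @param years Time points.
#' @param median_loss_pct Across-species median range loss per time
#'   (percent; positive values mean ranges shrank).
#' @param cum_area_km2 Cumulative converted area per time (km^2).
#' @return Data frame with columns `year`, `cum_area_km2`,
#'   `median_loss_pct`, and `marginal_loss_per_km2` (NA for the first row;
#'   NA where no new area was converted in the interval).
#' @export
marginal_loss_curve <- function(years, median_loss_pct, cum_area_km2) {
  if (length(median_loss_pct) != length(cum_area_km2) ||
      length(years) != length(cum_area_km2))
    stop("length mismatch between time, loss and area series")
  o <- order(years)
  y <- years[o]; l <- median_loss_pct[o]; a <- cum_area_km2[o]
  marg <- c(NA_real_, diff(l) / diff(a))
  marg[c(FALSE, diff(a) <= 0)] <- NA_real_
  data.frame(year = y, cum_area_km2 = a, median_loss_pct = l,
             marginal_loss_per_km2 = marg)
}

#' Map of the mean baseline range size of locally present species
#'
#' For each grid cell, the unweighted mean of the global baseline potential
#' range sizes of all species whose potential fraction in that cell is
#' positive. Cells where no species is present are `NA`.
#'
#' @param potential_fields List of baseline potential-range fraction matrices,
#'   one per species.
#' @param areas Cell-area matrix.
#' @return Matrix of mean range sizes in km^2 (`NA` where empty).
#' @export
local_mean_range_map <- function(potential_fields, areas) {
  if (!length(potential_fields)) stop("need at least one species")
  acc <- matrix(0, nrow(areas), ncol(areas))
  cnt <- matrix(0, nrow(areas), ncol(areas))
  for (f in potential_fields) {
    present <- f > 0
    acc <- acc + present * sum(f * areas)
    cnt <- cnt + present
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Bootstrap uncertainty of range-change percentiles
#'
#' Resamples the species-level range changes with replacement (resample size
#' equal to the input length), computes the requested percentiles per
#' resample, and summarises each percentile by its mean and standard
#' deviation across resamples. Reproducible for a given seed; the RNG is
#' R's default Mersenne-Twister.
#'
#' @param delta_pct Numeric vector of range changes (no `NA`s).
#' @param percentiles Percentile levels in percent.
#' @param n_boot Number of resamples (default 10000).
#' @param seed Integer seed (required).
#' @return Data frame with columns `percentile`, `mean`, `sd`.
#' @export
bootstrap_percentiles <- function(delta_pct, percentiles = seq(10, 90, by = 10),
                                  n_boot = 10000L, seed) {
  if (!length(delta_pct)) stop("empty input")
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(!anyNA(delta_pct))
  n <- length(delta_pct)
  probs <- percentiles / 100
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  qs <- matrix(0, n_boot, length(probs))
  for (b in seq_len(n_boot)) {
    qs[b, ] <- stats::quantile(delta_pct[sample.int(n, n, replace = TRUE)],
                               probs = probs, type = 7, names = FALSE)
  }
  data.frame(percentile = percentiles,
             mean = colMeans(qs),
             sd = apply(qs, 2, stats::sd))
}

#' Aggregate range-change curves across climate models
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) across
#' model-specific curves on a shared time grid. With a single model the SD
#' is undefined and returned as `NA`.
#'
#' @param curves Matrix with one column per climate model and one row per
#'   time point, or a list of equal-length numeric vectors.
#' @param years Optional time labels for the rows.
#' @return Data frame with columns `year` (if given), `mean`, `sd`, and
#'   `n_models`.
#' @export
scenario_aggregate <- function(curves, years = NULL) {
  if (is.list(curves) && !is.data.frame(curves)) {
    lens <- lengths(curves)
    if (length(unique(lens)) != 1L) stop("curves differ in length")
    curves <- do.call(cbind, curves)
  }
  m <- ncol(curves)
  out <- data.frame(mean = rowMeans(curves),
                    sd = if (m >= 2) apply(curves, 1, stats::sd) else NA_real_,
                    n_models = m)
  if (!is.null(years)) out <- cbind(data.frame(year = years), out)
  out
}
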