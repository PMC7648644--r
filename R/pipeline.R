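#' Scenario registry of emission / socio-economic combinations
#'
#' The registry is an explicit table of RCP/SSP combinations rather than a
#' rule, because the set of usable combinations is dictated by which
#' land-use projections exist. The default drops SSPs 1-4 under RCP 8.5,
#' leaving 16 of the 20 possible combinations.
#'
#' @param rcps,ssps Labels to cross.
#' @param exclude Data frame with columns `rcp`, `ssp` of combinations to
#'   drop.
#' @return Data frame with columns `rcp`, `ssp`.
#' @export
scenario_registry <- function(rcps = c("2.6", "4.5", "6.0", "8.5"),
                              ssps = as.character(1:5),
                              exclude = data.frame(
                                rcp = "8.5", ssp = as.character(1:4))) {
  combos <- expand.grid(rcp = rcps, ssp = ssps, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(combos$rcp, combos$ssp) %in% paste(exclude$rcp, exclude$ssp)
    combos <- combos[!drop, ]
  }
  combos <- combos[order(combos$rcp, combos$ssp), ]
  rownames(combos) <- NULL
  combos
}

#' Enumerate every pipeline run
#'
#' Historical runs cross the historical time points with the land-use
#' uncertainty variants; future runs cross the future time points with the
#' RCP/SSP registry and the climate models. With the default grids
#' (47 historical time points, 3 variants; 9 future time points, 16
#' combinations, 3 models) this yields 141 historical and 432 future runs.
#'
#' @param historical_years,future_years Time grids.
#' @param variants Land-use variant labels for the historical period.
#' @param combos RCP/SSP registry from [scenario_registry()].
#' @param models Climate-model labels.
#' @return List with data frames `historical` (`year`, `variant`) and
#'   `future` (`year`, `rcp`, `ssp`, `model`), plus `counts`.
#' @export
enumerate_runs <- function(historical_years = c(seq(1700L, 2000L, 10L), 2001:2016),
                           future_years = seq(2020L, 2100L, 10L),
                           variants = c("baseline", "lower", "upper"),
                           combos = scenario_registry(),
                           models = c("gcm1", "gcm2", "gcm3")) {
  if (!nrow(combos)) stop("empty scenario registry")
  if (anyDuplicated(paste(combos$rcp, combos$ssp)))
    stop("duplicate RCP/SSP combinations in registry")
  if (anyDuplicated(historical_years) || anyDuplicated(future_years))
    stop("duplicate time points")
  if (anyDuplicated(variants) || anyDuplicated(models))
    stop("duplicate variant or model labels")
  hist <- expand.grid(year = historical_years, variant = variants,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  fut <- merge(expand.grid(year = future_years, model = models,
                           stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
               cbind(combos, dummy = 1), by = NULL)
  fut$dummy <- NULL
  fut <- fut[order(fut$rcp, fut$ssp, fut$model, fut$year),
             c("year", "rcp", "ssp", "model")]
  rownames(fut) <- NULL
  list(historical = hist, future = fut,
       counts = c(historical_time_points = length(historical_years),
                  historical_runs = nrow(hist),
                  future_runs = nrow(fut)))
}

#' Stable hash of a configuration object
#' @noRd
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Range series for every species of a world under one input set
#' @noRd
world_range_table <- function(species, biomes, landuse, years, variant, mode,
                              t0, areas, mega = NULL, biomes_t0 = NULL) {
  rows <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[[i]]
    rs <- compute_range_series(sp, biomes, landuse, years = years,
                               variant = variant, mode = mode, t0 = t0,
                               areas = areas)
    rs$A_potential_t0 <- attr(rs, "A_potential_t0")
    rs$excluded <- attr(rs, "excluded")
    rows[[i]] <- rs
  }
  do.call(rbind, rows)
}

#' Run the full historical range pipeline on a synthetic world
#'
#' Computes, for every species, variant and historical time point, the
#' potential and actual range areas, the relative range change against the
#' 1850 baseline, and the climate-only change, then derives the
#' across-species summaries: percentile curves, critical-loss shares
#' (overall and by primary mega-biome), and the marginal-loss curve against
#' cumulative converted area. Excluded species (zero baseline) carry `NA`
#' changes. Output embeds a hash of the configuration, and the run is fully
#' deterministic, so re-running reproduces it identically.
#'
#' @param world A `synthetic_world` (or the analytic fixture's bundle — any
#'   list with `species`, `biomes`, `landuse`, `areas`, `mega_biomes`).
#' @param variants Variants to run (must exist in the world's land-use data).
#' @param mode Range-model mode, `"extended"` or `"strict"`.
#' @param t0 Reference year.
#' @param sensitivity `"main"` or `"no_migration"` (present-day filter
#'   applied to every species before the run).
#' @param present_year Year whose biome map defines "present" for the
#'   no-migration filter.
#' @return List of class `pipeline_result`: `ranges` (long data frame),
#'   `changes` (with `delta_pct`, `climate_only_pct`), `percentiles`,
#'   `critical` (per year), `critical_by_mega` (per year and mega-biome),
#'   `marginal` (baseline variant), `counts`, `config_hash`.
#' @export
run_pipeline <- function(world, variants = "baseline",
                         mode = c("extended", "strict"), t0 = 1850L,
                         sensitivity = c("main", "no_migration"),
                         present_year = 2016L) {
  mode <- match.arg(mode)
  sensitivity <- match.arg(sensitivity)
  species <- world$species
  years <- world$landuse$years
  areas <- world$areas
  biome_years <- vapply(world$biomes, function(b) b$year, integer(1))
  b_t0 <- world$biomes[[which.min(abs(biome_years - t0))]]
  # the baseline is always the main analysis' potential range: the
  # no-migration filter restricts where a species may persist, not what its
  # pre-industrial range was
  a_pot_t0 <- vapply(species, function(sp)
    range_area(potential_range_field(sp, b_t0), areas), numeric(1))
  if (sensitivity == "no_migration") {
    b_now <- world$biomes[[which.min(abs(biome_years - present_year))]]
    species <- lapply(species, no_migration_filter, biomes_present = b_now)
  }

  ranges <- do.call(rbind, lapply(variants, function(v) {
    tab <- world_range_table(species, world$biomes, world$landuse, years,
                             v, mode, t0, areas)
    tab$variant <- v
    tab
  }))
  ranges$A_potential_t0 <- a_pot_t0[ranges$species_id]
  ranges$excluded <- ranges$A_potential_t0 <= 0
  ranges$delta_pct <- range_change(ranges$A_actual_km2, ranges$A_potential_t0)
  ranges$climate_only_pct <- climate_only_change(ranges$A_potential_km2,
                                                 ranges$A_potential_t0)

  mega_of <- vapply(species, function(sp) {
    if (range_area(potential_range_field(sp, b_t0), areas) <= 0) NA_character_
    else primary_mega_biome(sp, b_t0, world$mega_biomes, areas)
  }, character(1))
  ranges$mega_biome <- mega_of[ranges$species_id]

  bl <- ranges[ranges$variant == variants[1], ]
  pct <- percentile_curves(bl[, c("year", "delta_pct")])
  crit <- do.call(rbind, lapply(split(bl, bl$year), function(d)
    data.frame(year = d$year[1],
               share = critical_loss_fraction(d$delta_pct))))
  crit_mega <- do.call(rbind, lapply(split(bl, bl$year), function(d) {
    keep <- !is.na(d$delta_pct)
    cbind(year = d$year[1],
          critical_loss_fraction(d$delta_pct[keep], groups = d$mega_biome[keep]))
  }))
  rownames(crit) <- rownames(crit_mega) <- NULL

  med <- tapply(bl$delta_pct, bl$year, stats::median, na.rm = TRUE)
  cum_area <- vapply(years, function(y)
    cumulative_converted_area(world$landuse, y, variants[1], areas), numeric(1))
  marginal <- marginal_loss_curve(years, -as.vector(med[as.character(years)]),
                                  cum_area)

  n_excluded <- sum(vapply(split(ranges$excluded, ranges$species_id), any,
                           logical(1)))
  structure(list(
    ranges = ranges[, c("species_id", "year", "variant", "A_potential_km2",
                        "A_actual_km2", "A_potential_t0", "excluded",
                        "delta_pct", "climate_only_pct", "mega_biome")],
    percentiles = pct, critical = crit, critical_by_mega = crit_mega,
    marginal = marginal,
    counts = c(n_species = length(species), n_excluded = n_excluded,
               n_years = length(years), n_variants = length(variants)),
    mode = mode, sensitivity = sensitivity, t0 = t0,
    config_hash = config_hash(list(mode = mode, sensitivity = sensitivity,
                                   t0 = t0, variants = variants,
                                   years = years))),
    class = "pipeline_result")
}

#' Run future scenarios for a synthetic world
#'
#' For each requested RCP/SSP combination and climate model, generates the
#' scenario's land use (harmonised at 2010) and biome maps via
#' [gen_future()], evaluates every species at the future time points, and
#' returns the long change table. With `static_biomes = TRUE` the biome maps
#' are frozen at the present-day map, the sensitivity run probing how much
#' of the projection is driven by biome shifts rather than land use.
#'
#' @param world A `synthetic_world`.
#' @param combos RCP/SSP registry (default [scenario_registry()]).
#' @param models Climate-model labels.
#' @param mode Range-model mode.
#' @param t0 Reference year (biome map nearest to it from the historical set).
#' @param sensitivity `"main"`, `"no_migration"` or `"static_biomes"`.
#' @param present_year Present-day year for the two sensitivity variants.
#' @return Long data frame: `species_id`, `year`, `rcp`, `ssp`, `model`,
#'   areas, `delta_pct`, `climate_only_pct`, `excluded`.
#' @export
run_future <- function(world, combos = scenario_registry(),
                       models = c("gcm1", "gcm2", "gcm3"),
                       mode = c("extended", "strict"), t0 = 1850L,
                       sensitivity = c("main", "no_migration", "static_biomes"),
                       present_year = 2016L) {
  mode <- match.arg(mode)
  sensitivity <- match.arg(sensitivity)
  areas <- world$areas
  biome_years <- vapply(world$biomes, function(b) b$year, integer(1))
  b_now <- world$biomes[[which.min(abs(biome_years - present_year))]]
  species <- world$species
  # the baseline potential range is defined on the historical biome maps and
  # on the unfiltered extent of occurrence, for every sensitivity variant
  b_t0 <- world$biomes[[which.min(abs(biome_years - t0))]]
  a_pot_t0 <- vapply(species, function(sp)
    range_area(potential_range_field(sp, b_t0), areas), numeric(1))
  if (sensitivity == "no_migration")
    species <- lapply(species, no_migration_filter, biomes_present = b_now)

  out <- list()
  for (ci in seq_len(nrow(combos))) for (m in models) {
    fut <- gen_future(world, combos$rcp[ci], combos$ssp[ci], m)
    biomes <- if (sensitivity == "static_biomes")
      lapply(fut$biomes, function(b) biome_map(b_now$codes, b$year, b_now$code_list))
    else fut$biomes
    tab <- world_range_table(species, biomes, fut$landuse,
                             world$cfg$future_years, "baseline", mode, t0, areas)
    # override the series-local baseline with the historical one
    tab$A_potential_t0 <- a_pot_t0[tab$species_id]
    tab$excluded <- tab$A_potential_t0 <= 0
    tab$rcp <- combos$rcp[ci]; tab$ssp <- combos$ssp[ci]; tab$model <- m
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  res$delta_pct <- range_change(res$A_actual_km2, res$A_potential_t0)
  res$climate_only_pct <- climate_only_change(res$A_potential_km2, res$A_potential_t0)
  rownames(res) <- NULL
  res
}
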