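#' Configuration of a synthetic world
#'
#' Bundles every knob of the synthetic-data generator: grid geometry, species
#' counts, logistic land-conversion parameters with a late-onset (tropical)
#' region, land-use uncertainty width, toy-climate trend parameters, and the
#' biome threshold table. Defaults describe a 60 x 30 degree regional window
#' at 0.5-degree resolution with 150 species, historical land use expanding
#' logistically with a mid-latitude midpoint of 1900 and a tropical midpoint
#' of 1985, so conversion reaches the tropics late — the pattern that
#' concentrates recent habitat loss among small-ranged tropical species.
#'
#' @param seed Integer seed (mandatory; drives every random draw).
#' @param resolution Coarse grid resolution in degrees.
#' @param lat_min,lat_max,lon_min,lon_max Grid extent in degrees.
#' @param n_species Named integer vector of species counts per group.
#' @param tropical_lat Half-width of the late-onset tropical band (degrees).
#' @param midpoint_temperate,midpoint_tropical Logistic midpoint years of the
#'   land-conversion trajectory outside/inside the tropical band.
#' @param growth_rate Logistic growth rate (1/year).
#' @param asymptote Maximum converted fraction a cell approaches.
#' @param uncertainty_halfwidth Relative half-width of the lower/upper
#'   land-use variants (0 collapses all variants onto the baseline).
#' @param class_shares Shares of cropland/pasture/urban in total conversion
#'   (must sum to 1).
#' @param warming_per_century Historical warming trend (degrees C per century,
#'   applied after 1900).
#' @param temp_threshold,precip_threshold Biome thresholds: annual-mean
#'   temperature cuts (cold/temperate and temperate/tropical, degrees C) and
#'   the humid/dry precipitation cut (mm/month).
#' @param historical_years,future_years Time grids.
#' @return An object of class `world_config`.
#' @export
world_config <- function(seed,
                         resolution = 0.5,
                         lat_min = -30, lat_max = 30,
                         lon_min = 0, lon_max = 30,
                         n_species = c(mammal = 50, bird = 50, amphibian = 50),
                         tropical_lat = 15,
                         midpoint_temperate = 1900,
                         midpoint_tropical = 1985,
                         growth_rate = 0.05,
                         asymptote = 0.85,
                         uncertainty_halfwidth = 0.1,
                         class_shares = c(cropland = 0.6, pasture = 0.3, urban = 0.1),
                         warming_per_century = 0.8,
                         temp_threshold = c(cold = 5, tropical = 18),
                         precip_threshold = 60,
                         historical_years = c(seq(1700L, 2000L, 10L), 2001:2016),
                         future_years = seq(2020L, 2100L, 10L)) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(asymptote > 0, asymptote <= 1,
            uncertainty_halfwidth >= 0, uncertainty_halfwidth < 1,
            abs(sum(class_shares) - 1) < 1e-9,
            all(class_shares >= 0), all(class_shares <= 1))
  if (asymptote * (1 + uncertainty_halfwidth) > 1)
    stop("asymptote * (1 + uncertainty_halfwidth) must not exceed 1")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "world_config")
}

#' Toy threshold biome classifier
#'
#' Classifies annual-mean climate into six biome codes from three temperature
#' bands crossed with two moisture bands:
#'
#' | code | band |
#' |------|------|
#' | 1 | tropical humid (T > 18, P > 60) |
#' | 2 | tropical dry |
#' | 3 | temperate humid (5 < T <= 18, P > 60) |
#' | 4 | temperate dry |
#' | 5 | cold humid (T <= 5, P > 60) |
#' | 6 | cold dry |
#'
#' Values exactly on a threshold fall into the lower (colder / drier) band.
#' This is a deliberately simple, fully documented stand-in for a process
#' vegetation model — it is not an emulation of one.
#'
#' @param temperature,precipitation `climate_field`s (monthly values are
#'   averaged to annual means) or plain matrices of annual means.
#' @param temp_threshold Two cuts, `c(cold = 5, tropical = 18)` degrees C.
#' @param precip_threshold Humid/dry cut in mm/month.
#' @param year Year label for the output map (taken from `temperature` if a
#'   `climate_field`).
#' @return A `biome_map` with code list 1:6.
#' @export
toy_biome_classify <- function(temperature, precipitation,
                               temp_threshold = c(cold = 5, tropical = 18),
                               precip_threshold = 60, year = NULL) {
  annual <- function(x) {
    if (inherits(x, "climate_field")) apply(x$data, c(1, 2), mean) else x
  }
  if (is.null(year)) {
    if (inherits(temperature, "climate_field")) year <- temperature$year
    else stop("year must be given when passing plain matrices")
  }
  t_ann <- annual(temperature); p_ann <- annual(precipitation)
  if (!identical(dim(t_ann), dim(p_ann)))
    stop("temperature and precipitation grids differ")
  band <- matrix(3L, nrow(t_ann), ncol(t_ann))       # cold
  band[t_ann > temp_threshold[["cold"]]] <- 2L       # temperate
  band[t_ann > temp_threshold[["tropical"]]] <- 1L   # tropical
  humid <- p_ann > precip_threshold
  codes <- (band - 1L) * 2L + ifelse(humid, 1L, 2L)
  biome_map(codes, year, code_list = 1:6)
}

#' Toy monthly climate for one year (deterministic trend + fixed pattern)
#' @noRd
toy_climate <- function(cfg, grid, year, warming_per_century = cfg$warming_per_century,
                        model_offset = 0) {
  cc <- cell_centres(grid)
  lat <- matrix(cc$lat, grid$nlat, grid$nlon)
  lon <- matrix(cc$lon, grid$nlat, grid$nlon, byrow = TRUE)
  # meridional gradient steep enough that the tropical/temperate boundary
  # (T = 18) stays inside a +/-30 degree domain even under strong warming
  warming <- warming_per_century * max(0, year - 1900) / 100 + model_offset
  t_ann <- 28 - 0.8 * abs(lat) + warming
  p_ann <- (25 + 105 * exp(-(lat / 18)^2)) * (0.62 + 0.38 * cos(2 * pi * lon / 30))
  amp <- 0.25 * abs(lat)
  tdat <- array(0, c(grid$nlat, grid$nlon, 12))
  pdat <- array(0, c(grid$nlat, grid$nlon, 12))
  for (m in 1:12) {
    season <- cos(2 * pi * (m - 7) / 12) * sign(lat + 1e-9)
    tdat[, , m] <- t_ann + amp * season
    pdat[, , m] <- pmax(p_ann * (1 + 0.2 * season), 0)
  }
  list(temperature = climate_field("temperature", year, grid, tdat),
       precipitation = climate_field("precipitation", year, grid, pdat))
}

#' Biome map of the toy world at one year
#' @noRd
toy_biomes_at <- function(cfg, grid, year, warming_per_century = cfg$warming_per_century,
                          model_offset = 0) {
  cl <- toy_climate(cfg, grid, year, warming_per_century, model_offset)
  toy_biome_classify(cl$temperature, cl$precipitation,
                     cfg$temp_threshold, cfg$precip_threshold)
}

#' Default habitat-category crosswalk of the synthetic world
#'
#' One natural category per toy biome (`H1`..`H6`, no artificial classes)
#' plus one category per artificial class (`A_cropland`, `A_pasture`,
#' `A_urban`, no biomes).
#' @return A `habitat_crosswalk`.
#' @export
toy_crosswalk <- function() {
  df <- data.frame(
    category = c(paste0("H", 1:6), paste0("A_", LU_CLASSES)),
    biomes = c(as.character(1:6), "", "", ""),
    cropland = c(rep(0, 6), 1, 0, 0),
    pasture = c(rep(0, 6), 0, 1, 0),
    urban = c(rep(0, 6), 0, 0, 1)
  )
  as_crosswalk(df, biome_codes = 1:6)
}

#' Mega-biome grouping of the six toy biomes
#'
#' @return Data frame mapping biome code to mega-biome label
#'   (tropical / temperate / boreal).
#' @export
toy_mega_biomes <- function() {
  data.frame(biome = 1:6,
             mega_biome = rep(c("tropical", "temperate", "boreal"), each = 2))
}

#' Generate a full synthetic input bundle
#'
#' Builds, reproducibly from the seed, everything the range pipeline
#' ingests: the coarse/fine grid pair, cell areas, a habitat crosswalk,
#' random species (rectangular extents of occurrence with log-uniform sizes;
#' species centred in the tropical band draw smaller ranges), a historical
#' land-use series with three variants (`lower <= baseline <= upper`,
#' monotone logistic growth, late-onset conversion in the tropics), and
#' decadal biome maps classified from the toy climate.
#'
#' @param cfg A `world_config`.
#' @return An object of class `synthetic_world`: list with elements `cfg`,
#'   `grid`, `fine_grid`, `areas`, `crosswalk`, `mega_biomes`, `species`
#'   (list of `species_record`), `polygons` (the generating rectangles),
#'   `landuse` (`landuse_series`), `biomes` (list of decadal `biome_map`s),
#'   and `tropical_mask` (logical matrix of the late-onset band).
#' @export
gen_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  grid <- grid_spec(cfg$resolution, cfg$lat_min, cfg$lat_max, cfg$lon_min, cfg$lon_max)
  fine_grid <- refine_grid(grid, 6L)
  areas <- cell_areas(grid)
  cc <- cell_centres(grid)
  lat <- matrix(cc$lat, grid$nlat, grid$nlon)
  lon <- matrix(cc$lon, grid$nlat, grid$nlon, byrow = TRUE)
  tropical_mask <- abs(lat) < cfg$tropical_lat

  # --- land use: per-cell logistic conversion, late onset in the tropics ---
  midpoint <- ifelse(tropical_mask, cfg$midpoint_tropical, cfg$midpoint_temperate) +
    matrix(stats::rnorm(grid$nlat * grid$nlon, 0, 5), grid$nlat, grid$nlon)
  asym <- cfg$asymptote *
    matrix(stats::runif(grid$nlat * grid$nlon, 0.5, 1), grid$nlat, grid$nlon)
  yrs <- cfg$historical_years
  base <- array(0, c(grid$nlat, grid$nlon, 3, length(yrs)),
                dimnames = list(NULL, NULL, LU_CLASSES, yrs))
  for (i in seq_along(yrs)) {
    f_tot <- asym * stats::plogis(cfg$growth_rate * (yrs[i] - midpoint))
    for (k in LU_CLASSES) base[, , k, i] <- f_tot * cfg$class_shares[[k]]
  }
  h <- cfg$uncertainty_halfwidth
  lu <- landuse_series(grid, yrs, list(baseline = base,
                                       lower = base * (1 - h),
                                       upper = base * (1 + h)))

  # --- biome maps at decadal steps of the historical period ---
  biome_years <- seq(min(yrs) - min(yrs) %% 10, max(yrs) + 4, by = 10)
  biomes <- lapply(biome_years, function(y) toy_biomes_at(cfg, grid, y))

  # --- species: rectangular extents, smaller in the tropics ---
  b1850 <- biomes[[which.min(abs(biome_years - 1850))]]
  xw <- toy_crosswalk()
  species <- list(); polygons <- list()
  idx <- 0L
  for (g in names(cfg$n_species)) {
    for (s in seq_len(cfg$n_species[[g]])) {
      idx <- idx + 1L
      in_tropics <- stats::runif(1) < 0.5
      clat <- if (in_tropics) stats::runif(1, -cfg$tropical_lat, cfg$tropical_lat)
              else sample(c(-1, 1), 1) * stats::runif(1, cfg$tropical_lat, cfg$lat_max - 2)
      clon <- stats::runif(1, cfg$lon_min + 2, cfg$lon_max - 2)
      size_scale <- if (in_tropics) 0.35 else 1
      half <- exp(stats::runif(1, log(0.75), log(8))) * size_scale
      ring <- cbind(
        lon = pmin(pmax(c(clon - half, clon + half, clon + half, clon - half),
                        cfg$lon_min), cfg$lon_max),
        lat = pmin(pmax(c(clat - half, clat - half, clat + half, clat + half),
                        cfg$lat_min), cfg$lat_max))
      eoo <- polygon_coverage(ring, fine_grid, grid)
      # suitability: biomes present in the EOO at 1850, thinned at random,
      # always keeping the modal one so the baseline range is nonzero
      present <- b1850$codes[eoo > 0]
      if (!length(present)) next  # EOO missed every fine-cell centre
      modal <- as.integer(names(which.max(table(present))))
      extra <- setdiff(unique(present), modal)
      keep <- extra[stats::runif(length(extra)) < 0.4]
      cats <- paste0("H", sort(c(modal, keep)))
      cats <- c(cats, c("A_cropland", "A_pasture", "A_urban")[
        stats::runif(3) < c(0.25, 0.4, 0.05)])
      suit <- species_suitability(cats, xw)
      sid <- sprintf("%s_%03d", g, s)
      species[[sid]] <- species_record(sid, g, eoo, suit$suitable_biomes,
                                       suit$suitable_artificial, grid)
      polygons[[sid]] <- ring
    }
  }
  n_dropped <- sum(cfg$n_species) - length(species)
  if (n_dropped > 0)
    message(n_dropped, " species dropped: extent of occurrence overlapped no grid cell")

  structure(list(cfg = cfg, grid = grid, fine_grid = fine_grid, areas = areas,
                 crosswalk = xw, mega_biomes = toy_mega_biomes(),
                 species = species, polygons = polygons,
                 landuse = lu, biomes = biomes, tropical_mask = tropical_mask),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d species, %d x %d cells, %d land-use years, %d biome maps\n",
              length(x$species), x$grid$nlat, x$grid$nlon,
              length(x$landuse$years), length(x$biomes)))
  invisible(x)
}

#' Future land-use and biome projections for the synthetic world
#'
#' Extends a synthetic world beyond the historical period for one
#' emission/socio-economic scenario. Land use continues from a slightly
#' perturbed copy of the 2010 state (emulating a projection model whose
#' present-day state disagrees with the reconstruction, so harmonisation is
#' exercised), growing or shrinking by an SSP-specific trend that is
#' strongest in the late-onset tropical band for the high-pressure pathway.
#' Future biome maps are classified from the toy climate under an
#' RCP-specific warming rate, with a small model-specific temperature offset
#' per climate model label.
#'
#' @param world A `synthetic_world`.
#' @param rcp RCP label, one of `"2.6"`, `"4.5"`, `"6.0"`, `"8.5"`.
#' @param ssp SSP label, one of `"1"`..`"5"`.
#' @param model Climate-model label, one of `"gcm1"`, `"gcm2"`, `"gcm3"`.
#' @param harmonise If `TRUE` (default) anchor the projection to the
#'   historical series at the 2010 junction via [harmonise_future()].
#' @return List with `landuse` (a `landuse_series` on the future time grid)
#'   and `biomes` (list of decadal `biome_map`s).
#' @export
gen_future <- function(world, rcp = "6.0", ssp = "3", model = "gcm1",
                       harmonise = TRUE) {
  cfg <- world$cfg
  grid <- world$grid
  warming <- c("2.6" = 1.2, "4.5" = 2.2, "6.0" = 3.0, "8.5" = 4.3)[[rcp]]
  trend <- c("1" = -0.35, "2" = 0.20, "3" = 0.60, "4" = 0.35, "5" = 0.30)[[ssp]]
  offs <- c(gcm1 = -1.0, gcm2 = 0, gcm3 = 1.0)[[model]]
  yrs <- cfg$future_years
  # projection-model present state: multiplicative bias so the junction delta
  # is nonzero and harmonisation has something to correct
  f2010 <- vapply(LU_CLASSES, function(k) lu_layer(world$landuse, k, 2010L),
                  matrix(0, grid$nlat, grid$nlon))
  bias <- 0.95
  growth_mask <- 1 + 0.5 * world$tropical_mask  # tropics convert fastest
  fut <- array(0, c(grid$nlat, grid$nlon, 3, length(yrs)),
               dimnames = list(NULL, NULL, LU_CLASSES, yrs))
  for (i in seq_along(yrs)) {
    scale <- pmax(1 + trend * growth_mask * (yrs[i] - 2010) / 90, 0)
    for (k in LU_CLASSES)
      fut[, , k, i] <- pmin(f2010[, , k] * bias * scale, 0.95 * cfg$class_shares[[k]])
  }
  fut_all <- array(0, c(grid$nlat, grid$nlon, 3, length(yrs) + 1L),
                   dimnames = list(NULL, NULL, LU_CLASSES, c(2010L, yrs)))
  fut_all[, , , 1] <- f2010 * bias
  fut_all[, , , -1] <- fut
  fut_series <- landuse_series(grid, c(2010L, yrs), list(baseline = fut_all))
  if (harmonise)
    fut_series <- harmonise_future(world$landuse, fut_series, 2010L)
  biome_yrs <- seq(2020L, max(yrs), 10L)
  biomes <- lapply(biome_yrs, function(y)
    toy_biomes_at(cfg, grid, y, warming_per_century = warming,
                  model_offset = offs * max(0, y - 2006) / 94))
  list(landuse = fut_series, biomes = biomes, rcp = rcp, ssp = ssp, model = model)
}
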