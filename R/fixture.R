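#' Exactly solvable 4 x 4 fixture world
#'
#' A tiny world whose every output can be verified by hand, used as the
#' end-to-end oracle for the range pipeline. The grid is 4 x 4 cells of
#' 0.5 degrees spanning lat/lon \[0, 2\]; each species' extent of occurrence
#' is confined to a single latitude row, so per-row cell areas factor out of
#' all relative statistics and the expected range changes are exact
#' rationals. The two row-area constants were evaluated independently from
#' the spherical-zone formula and are frozen here.
#'
#' The cast (habitat categories resolve through [toy_crosswalk()]-style
#' rules stored in the fixture's own crosswalk):
#'
#' * species A (`mam_A`): natural-habitat specialist on biome 1 occupying all
#'   of row 2; cropland (which it cannot use) expands inside its range, and
#'   one of its cells flips to an unsuitable biome at the last time point.
#' * species B (`bird_B`): tolerates cropland; half of its two-cell extent
#'   lies on an unsuitable biome that is progressively converted to
#'   cropland, so its range expands in extended mode but is flat in strict
#'   mode.
#' * species C (`amph_C`): requires a biome absent from its extent, so its
#'   baseline potential range is zero and it is excluded.
#'
#' @return List with elements `grid`, `areas`, `years` (1850, 1950, 2016),
#'   `biomes` (list of `biome_map`s), `landuse` (`landuse_series`),
#'   `crosswalk`, `mega_biomes`, `species` (list of `species_record`s), and
#'   `expected`: the hand-computed ledger with `ranges` (per species, year
#'   and mode: areas in km^2, range change and climate-only change in
#'   percent), `excluded`, `percentiles_2016_extended` (10/50/90), and
#'   `critical_share` per year and mode (threshold 50).
#' @export
analytic_fixture <- function() {
  grid <- grid_spec(0.5, lat_min = 0, lat_max = 2, lon_min = 0, lon_max = 2)
  areas <- cell_areas(grid)
  years <- c(1850L, 1950L, 2016L)

  # independently evaluated spherical-zone areas (R = 6371 km, 0.5 deg lon):
  a2 <- 3090.3325290813486  # row 2: lat [1.0, 1.5]
  a3 <- 3090.8033002832512  # row 3: lat [0.5, 1.0]

  base_codes <- matrix(1L, 4, 4)
  base_codes[3, 2] <- 2L                      # species B's unsuitable cell
  codes_2016 <- base_codes
  codes_2016[2, 4] <- 2L                      # flips out of A's suitable set
  biomes <- list(biome_map(base_codes, 1850L, 1:2),
                 biome_map(base_codes, 1950L, 1:2),
                 biome_map(codes_2016, 2016L, 1:2))

  zero <- matrix(0, 4, 4)
  crop_1950 <- zero; crop_1950[2, 1:2] <- 0.25; crop_1950[3, 2] <- 0.4
  crop_2016 <- zero; crop_2016[2, ] <- 0.5;     crop_2016[3, 2] <- 0.8
  lu_arr <- array(0, c(4, 4, 3, 3), dimnames = list(NULL, NULL, LU_CLASSES, years))
  lu_arr[, , "cropland", 2] <- crop_1950
  lu_arr[, , "cropland", 3] <- crop_2016
  landuse <- landuse_series(grid, years, list(baseline = lu_arr))

  xw <- as_crosswalk(data.frame(
    category = c("F", "G", "A_cropland"),
    biomes = c("1", "2", ""),
    cropland = c(0, 0, 1), pasture = c(0, 0, 0), urban = c(0, 0, 0)),
    biome_codes = 1:2)
  mega <- data.frame(biome = 1:2, mega_biome = c("forest", "grassland"))

  eoo_a <- zero; eoo_a[2, ] <- 1
  eoo_b <- zero; eoo_b[3, 1:2] <- 1
  eoo_c <- zero; eoo_c[4, 1] <- 1
  mk <- function(id, group, eoo, cats) {
    s <- species_suitability(cats, xw)
    species_record(id, group, eoo, s$suitable_biomes, s$suitable_artificial, grid)
  }
  species <- list(
    mam_A = mk("mam_A", "mammal", eoo_a, "F"),
    bird_B = mk("bird_B", "bird", eoo_b, c("F", "A_cropland")),
    amph_C = mk("amph_C", "amphibian", eoo_c, "G"))

  # ---- hand-computed ledger ------------------------------------------------
  # Species A (row 2, area unit a2). Potential fractions: 4, 4, 3.
  #   Actual 1950: 2*(1-0.25) + 2*1 = 3.5; actual 2016: 3*(1-0.5) = 1.5.
  #   dA = 100*(act/4 - 1): 0, -12.5, -62.5; climate-only: 0, 0, -25.
  # Species B (row 3, area unit a3). Potential: 1 at all times (cell (3,1)).
  #   Extended actual: 1, 1 + 0.4, 1 + 0.8 -> dA 0, +40, +80.
  #   Strict actual: 1, 1, 1 -> dA 0, 0, 0; climate-only: 0, 0, 0.
  ranges <- rbind(
    data.frame(species_id = "mam_A", mode = "extended", year = years,
               A_potential_km2 = c(4, 4, 3) * a2,
               A_actual_km2 = c(4, 3.5, 1.5) * a2,
               delta_pct = c(0, -12.5, -62.5),
               climate_only_pct = c(0, 0, -25)),
    data.frame(species_id = "mam_A", mode = "strict", year = years,
               A_potential_km2 = c(4, 4, 3) * a2,
               A_actual_km2 = c(4, 3.5, 1.5) * a2,
               delta_pct = c(0, -12.5, -62.5),
               climate_only_pct = c(0, 0, -25)),
    data.frame(species_id = "bird_B", mode = "extended", year = years,
               A_potential_km2 = c(1, 1, 1) * a3,
               A_actual_km2 = c(1, 1.4, 1.8) * a3,
               delta_pct = c(0, 40, 80),
               climate_only_pct = c(0, 0, 0)),
    data.frame(species_id = "bird_B", mode = "strict", year = years,
               A_potential_km2 = c(1, 1, 1) * a3,
               A_actual_km2 = c(1, 1, 1) * a3,
               delta_pct = c(0, 0, 0),
               climate_only_pct = c(0, 0, 0)))

  # Percentiles over included species {A, B} at 2016, extended mode, with
  # linear interpolation between the two order statistics {-62.5, 80}:
  #   q(p) = -62.5 + p * 142.5  ->  q(0.1) = -48.25, q(0.5) = 8.75,
  #   q(0.9) = 65.75.
  expected <- list(
    ranges = ranges,
    excluded = c(mam_A = FALSE, bird_B = FALSE, amph_C = TRUE),
    primary_mega_biome = c(mam_A = "forest", bird_B = "forest"),
    percentiles_2016_extended = data.frame(
      percentile = c(10, 50, 90), value = c(-48.25, 8.75, 65.75)),
    median_extended = data.frame(year = years, value = c(0, 13.75, 8.75)),
    median_strict = data.frame(year = years, value = c(0, -6.25, -31.25)),
    critical_share = data.frame(
      year = rep(years, 2),
      mode = rep(c("extended", "strict"), each = 3),
      share = c(0, 0, 0.5, 0, 0, 0.5)))

  list(grid = grid, areas = areas, years = years, biomes = biomes,
       landuse = landuse, crosswalk = xw, mega_biomes = mega,
       species = species, expected = expected)
}
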