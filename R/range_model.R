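#' Habitat-category to biome crosswalk
#'
#' A crosswalk table links each habitat-classification category to the set of
#' potential-natural biome codes it corresponds to, plus flags for the
#' artificial land-cover classes (cropland, pasture, urban) that the category
#' legitimises. The expected CSV schema is:
#' `category, biomes, cropland, pasture, urban`, where `biomes` is a
#' semicolon-separated list of integer biome codes (may be empty) and the
#' flag columns are 0/1.
#'
#' @param path Path to a crosswalk CSV.
#' @param biome_codes Optional integer vector of valid biome codes; referenced
#'   codes outside this set raise an error.
#' @return A data.frame of class `habitat_crosswalk` with list-column
#'   `biomes` and logical artificial-class columns.
#' @export
read_crosswalk <- function(path, biome_codes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_crosswalk(df, biome_codes)
}

#' @rdname read_crosswalk
#' @param df Data frame with the crosswalk CSV schema.
#' @export
as_crosswalk <- function(df, biome_codes = NULL) {
  stopifnot(all(c("category", "biomes", "cropland", "pasture", "urban") %in% names(df)))
  parse_codes <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer(0))
    as.integer(strsplit(trimws(s), ";")[[1]])
  }
  biomes <- lapply(as.character(df$biomes), parse_codes)
  if (!is.null(biome_codes)) {
    bad <- setdiff(unique(unlist(biomes)), biome_codes)
    if (length(bad))
      stop("crosswalk references unknown biome codes: ", paste(bad, collapse = ", "))
  }
  out <- data.frame(category = as.character(df$category))
  out$biomes <- biomes
  for (k in LU_CLASSES) out[[k]] <- as.logical(df[[k]])
  class(out) <- c("habitat_crosswalk", "data.frame")
  out
}

#' Derive species suitability sets from habitat categories
#'
#' Unions the biome codes of all of a species' habitat categories and flags
#' an artificial class as suitable if any category legitimises it.
#'
#' @param categories Character vector of habitat-category codes.
#' @param crosswalk A `habitat_crosswalk`.
#' @return List with `suitable_biomes` (integer vector) and
#'   `suitable_artificial` (character subset of cropland/pasture/urban).
#' @export
species_suitability <- function(categories, crosswalk) {
  idx <- match(categories, crosswalk$category)
  if (anyNA(idx))
    stop("unknown habitat categories: ",
         paste(categories[is.na(idx)], collapse = ", "))
  list(
    suitable_biomes = sort(unique(unlist(crosswalk$biomes[idx]))),
    suitable_artificial = LU_CLASSES[vapply(LU_CLASSES, function(k)
      any(crosswalk[[k]][idx]), logical(1))]
  )
}

#' Species record: gridded extent of occurrence plus suitability sets
#'
#' @param species_id Identifier string.
#' @param group One of `"mammal"`, `"bird"`, `"amphibian"`.
#' @param eoo_fraction Matrix of extent-of-occurrence coverage fractions on
#'   the coarse grid (from [polygon_coverage()]), values in \[0, 1\].
#' @param suitable_biomes Integer vector of suitable biome codes.
#' @param suitable_artificial Character subset of
#'   `c("cropland", "pasture", "urban")`.
#' @param grid The `grid_spec` the coverage field lives on.
#' @return An object of class `species_record`.
#' @export
species_record <- function(species_id, group, eoo_fraction, suitable_biomes,
                           suitable_artificial = character(0), grid) {
  group <- match.arg(group, c("mammal", "bird", "amphibian"))
  stopifnot(inherits(grid, "grid_spec"),
            nrow(eoo_fraction) == grid$nlat, ncol(eoo_fraction) == grid$nlon)
  if (any(eoo_fraction < -1e-12) || any(eoo_fraction > 1 + 1e-12))
    stop("eoo_fraction outside [0, 1]")
  bad <- setdiff(suitable_artificial, LU_CLASSES)
  if (length(bad)) stop("unknown artificial classes: ", paste(bad, collapse = ", "))
  structure(list(species_id = as.character(species_id), group = group,
                 eoo_fraction = pmin(pmax(eoo_fraction, 0), 1),
                 suitable_biomes = as.integer(suitable_biomes),
                 suitable_artificial = suitable_artificial, grid = grid),
            class = "species_record")
}

#' Categorical biome map at one time
#'
#' @param codes Integer matrix of biome codes.
#' @param year Calendar year the map corresponds to.
#' @param code_list Declared integer code list; every cell must use one.
#' @return An object of class `biome_map`.
#' @export
biome_map <- function(codes, year, code_list = sort(unique(as.vector(codes)))) {
  if (!all(codes %in% code_list))
    stop("biome map contains codes outside the declared code list")
  structure(list(codes = codes, year = as.integer(year),
                 code_list = as.integer(code_list)), class = "biome_map")
}

#' @noRd
check_aligned <- function(sp, mat, what) {
  if (!identical(dim(sp$eoo_fraction), dim(mat)))
    stop("grid mismatch between species field and ", what)
}

#' Potential natural range field of a species
#'
#' Subsets the extent of occurrence by biome suitability: per cell, the
#' coverage fraction is retained only where the local potential natural
#' biome is in the species' suitable set.
#'
#' @param sp A `species_record`.
#' @param biomes A `biome_map` on the same grid.
#' @return Matrix of habitat fractions.
#' @export
potential_range_field <- function(sp, biomes) {
  check_aligned(sp, biomes$codes, "biome map")
  sp$eoo_fraction * (biomes$codes %in% sp$suitable_biomes)
}

#' Actual range field of a species under land use
#'
#' Splits each cell into a natural remainder `1 - sum(f_k)` and the
#' artificial class fractions `f_k` (cropland, pasture, urban), and retains
#' the parts the species tolerates:
#'
#' * `"extended"` (default): the natural remainder counts where the natural
#'   biome is suitable, and each artificial fraction counts wherever that
#'   class is suitable — including cells whose natural biome is unsuitable.
#'   This is what lets conversion of unsuitable natural vegetation to
#'   tolerated cropland or pasture expand a range.
#' * `"strict"`: artificial fractions are only counted in cells whose
#'   natural biome is suitable, so the actual range is always a subset of
#'   the potential range at the same time.
#'
#' @param sp A `species_record`.
#' @param biomes A `biome_map`.
#' @param lu Named list of class-fraction matrices
#'   (`cropland`, `pasture`, `urban`).
#' @param mode `"extended"` or `"strict"`.
#' @return Matrix of habitat fractions.
#' @export
actual_range_field <- function(sp, biomes, lu, mode = c("extended", "strict")) {
  mode <- match.arg(mode)
  check_aligned(sp, biomes$codes, "biome map")
  for (k in LU_CLASSES) check_aligned(sp, lu[[k]], paste0(k, " layer"))
  f_sum <- lu$cropland + lu$pasture + lu$urban
  if (any(f_sum > 1 + 1e-6)) stop("land-use class fractions sum above 1")
  f_sum <- pmin(f_sum, 1)
  nat_ok <- biomes$codes %in% sp$suitable_biomes
  art <- matrix(0, nrow(f_sum), ncol(f_sum))
  for (k in intersect(sp$suitable_artificial, LU_CLASSES)) art <- art + lu[[k]]
  hab <- switch(mode,
    extended = (1 - f_sum) * nat_ok + art,
    strict = nat_ok * ((1 - f_sum) + art))
  sp$eoo_fraction * hab
}

#' Range size in km^2 of a habitat-fraction field
#'
#' @param field Matrix of habitat fractions.
#' @param areas Cell-area matrix from [cell_areas()].
#' @return Total area in km^2.
#' @export
range_area <- function(field, areas) {
  if (!identical(dim(field), dim(areas))) stop("grid mismatch")
  sum(field * areas)
}

#' No-migration filter: restrict a species to presently suitable cells
#'
#' Zeroes the extent-of-occurrence fraction in every cell whose present-day
#' biome is not in the species' suitable set, so future ranges computed from
#' the filtered record only count cells suitable both now and then. Range
#' fields under the filtered record are pointwise subsets of the unfiltered
#' ones, so projected losses are, by construction, at least as large.
#'
#' @param sp A `species_record`.
#' @param biomes_present Present-day `biome_map`.
#' @return A filtered `species_record`.
#' @export
no_migration_filter <- function(sp, biomes_present) {
  check_aligned(sp, biomes_present$codes, "present-day biome map")
  eoo <- sp$eoo_fraction * (biomes_present$codes %in% sp$suitable_biomes)
  species_record(sp$species_id, sp$group, eoo, sp$suitable_biomes,
                 sp$suitable_artificial, sp$grid)
}

#' Nearest available year (ties to the earlier year)
#' @noRd
nearest_year <- function(target, available) {
  available[which.min(abs(available - target))]
}

#' Potential and actual range sizes of a species through time
#'
#' For every requested year, pairs the land-use layers with the temporally
#' nearest biome map (ties to the earlier map), computes the potential and
#' actual habitat fields, and integrates them to areas. Species with zero
#' potential range at the reference year are flagged `excluded`, since
#' relative range changes are undefined for them.
#'
#' @param sp A `species_record`.
#' @param biome_maps List of `biome_map`s (any years; nearest is used).
#' @param lu_series A `landuse_series` containing all requested years.
#' @param years Years to evaluate (default: the land-use series years).
#' @param variant Land-use variant.
#' @param mode Passed to [actual_range_field()].
#' @param t0 Reference year for the baseline potential range (default 1850).
#' @param areas Cell-area matrix.
#' @return Data frame with columns `species_id`, `year`, `A_potential_km2`,
#'   `A_actual_km2`, plus attributes `excluded` (logical) and
#'   `A_potential_t0` (km^2).
#' @export
compute_range_series <- function(sp, biome_maps, lu_series,
                                 years = lu_series$years,
                                 variant = "baseline",
                                 mode = c("extended", "strict"),
                                 t0 = 1850L,
                                 areas = cell_areas(sp$grid)) {
  mode <- match.arg(mode)
  if (!length(years)) stop("empty time grid")
  biome_years <- vapply(biome_maps, function(b) b$year, integer(1))
  biome_at <- function(y) biome_maps[[which.min(abs(biome_years - y))]]
  a_pot <- a_act <- numeric(length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    b <- biome_at(y)
    pot <- potential_range_field(sp, b)
    act <- actual_range_field(sp, b, lu_classes_at(lu_series, y, variant), mode)
    a_pot[i] <- range_area(pot, areas)
    a_act[i] <- range_area(act, areas)
  }
  a_pot_t0 <- range_area(potential_range_field(sp, biome_at(t0)), areas)
  out <- data.frame(species_id = sp$species_id, year = years,
                    A_potential_km2 = a_pot, A_actual_km2 = a_act)
  attr(out, "A_potential_t0") <- a_pot_t0
  attr(out, "excluded") <- a_pot_t0 <= 0
  out
}
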