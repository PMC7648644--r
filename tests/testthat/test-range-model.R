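# two-cell grid used throughout: one row, two columns
g12 <- grid_spec(1, 0, 1, 0, 2)

sp2 <- function(eoo = c(1, 1), biomes = 1L, art = character(0)) {
  species_record("sp", "mammal", matrix(eoo, 1, 2), biomes, art, g12)
}
bm2 <- function(codes, year = 1850) biome_map(matrix(codes, 1, 2), year, 1:2)
lu2 <- function(crop = c(0, 0), past = c(0, 0), urb = c(0, 0)) {
  list(cropland = matrix(crop, 1, 2), pasture = matrix(past, 1, 2),
       urban = matrix(urb, 1, 2))
}

test_that("crosswalk resolves habitat categories to suitability sets", {
  xw <- as_crosswalk(data.frame(
    category = c("wood", "grass", "farm"),
    biomes = c("1;3", "2", ""),
    cropland = c(0, 0, 1), pasture = c(0, 1, 1), urban = c(0, 0, 0)),
    biome_codes = 1:3)
  s <- species_suitability(c("wood", "farm"), xw)
  expect_equal(s$suitable_biomes, c(1L, 3L))
  expect_equal(s$suitable_artificial, c("cropland", "pasture"))
  expect_error(species_suitability("river", xw), "unknown habitat")
  expect_error(as_crosswalk(data.frame(category = "x", biomes = "9",
                                       cropland = 0, pasture = 0, urban = 0),
                            biome_codes = 1:3), "unknown biome")
})

test_that("potential range is the biome-filtered extent of occurrence", {
  sp <- sp2(eoo = c(1, 0.5))
  # all biomes suitable -> equals the coverage field
  expect_equal(potential_range_field(sp2(eoo = c(0.3, 0.8), biomes = 1:2),
                                     bm2(c(1, 2))),
               matrix(c(0.3, 0.8), 1, 2))
  # empty suitable set -> zero field
  expect_equal(potential_range_field(sp2(biomes = integer(0)), bm2(c(1, 1))),
               matrix(0, 1, 2))
  # indicator per cell: eoo (1, 0.5), biomes (suitable, unsuitable)
  expect_equal(potential_range_field(sp, bm2(c(1, 2))), matrix(c(1, 0), 1, 2))
  expect_error(potential_range_field(sp, biome_map(matrix(1, 2, 2), 1850)),
               "mismatch")
})

test_that("actual range splits cells by land-cover suitability", {
  # zero land use everywhere -> equals the potential range
  sp <- sp2(eoo = c(1, 0.5))
  b <- bm2(c(1, 2))
  expect_equal(actual_range_field(sp, b, lu2()), potential_range_field(sp, b))
  # suitable everywhere (natural + all artificial) -> equals eoo regardless
  all_ok <- sp2(eoo = c(0.9, 0.4), biomes = 1:2,
                art = c("cropland", "pasture", "urban"))
  expect_equal(actual_range_field(all_ok, b, lu2(crop = c(0.5, 0.2),
                                                 past = c(0.1, 0.3))),
               matrix(c(0.9, 0.4), 1, 2))
  # hand case: eoo 1, natural suitable, cropland 0.3 (unsuitable),
  # pasture 0.1 (suitable), urban 0 -> 0.6 * 1 + 0.1 = 0.7
  sp_p <- sp2(eoo = c(1, 0), art = "pasture")
  out <- actual_range_field(sp_p, bm2(c(1, 1)), lu2(crop = c(0.3, 0),
                                                    past = c(0.1, 0)))
  expect_equal(out[1, 1], 0.7)
  expect_error(actual_range_field(sp, b, lu2(crop = c(0.8, 0),
                                             past = c(0.5, 0))), "sum above 1")
})

test_that("extended mode can exceed potential, strict mode cannot", {
  # species tolerates cropland; cell 2's natural biome is unsuitable and 60%
  # cropland: extended counts the cropland there, strict does not
  sp <- sp2(eoo = c(1, 1), biomes = 1L, art = "cropland")
  b <- bm2(c(1, 2))
  lu <- lu2(crop = c(0, 0.6))
  ext <- actual_range_field(sp, b, lu, mode = "extended")
  str <- actual_range_field(sp, b, lu, mode = "strict")
  pot <- potential_range_field(sp, b)
  expect_equal(ext, matrix(c(1, 0.6), 1, 2))
  expect_equal(str, matrix(c(1, 0), 1, 2))
  expect_true(all(str <= pot + 1e-12))
  expect_gt(sum(ext), sum(pot))  # the expansion pathway
  # both stay within the extent of occurrence pointwise
  expect_true(all(ext <= sp$eoo_fraction + 1e-12))
  expect_true(all(pot <= sp$eoo_fraction + 1e-12))
})

test_that("range area integrates fractions against cell areas", {
  areas <- matrix(c(1000, 2000), 1, 2)
  expect_equal(range_area(matrix(c(0.25, 0.5), 1, 2), areas), 1250)
  expect_equal(range_area(matrix(0, 1, 2), areas), 0)
  expect_equal(range_area(matrix(1, 1, 2), areas), 3000)
  expect_error(range_area(matrix(0, 2, 2), areas), "mismatch")
})

test_that("adding unsuitable artificial cover never grows the actual range", {
  set.seed(9)
  w <- small_world()
  areas <- cell_areas(w$grid)
  b <- w$biomes[[20]]
  viol <- 0L
  for (rep in 1:200) {
    sp <- w$species[[sample(length(w$species), 1)]]
    unsuit <- setdiff(c("cropland", "pasture", "urban"), sp$suitable_artificial)
    if (!length(unsuit)) next
    k <- sample(unsuit, 1)
    base_lu <- stats::setNames(lapply(
      c("cropland", "pasture", "urban"), function(cl)
        matrix(runif(w$grid$nlat * w$grid$nlon, 0, 0.3),
               w$grid$nlat, w$grid$nlon)), c("cropland", "pasture", "urban"))
    a0 <- range_area(actual_range_field(sp, b, base_lu), areas)
    # bump the unsuitable class (shrinking the natural remainder)
    pert <- base_lu
    pert[[k]] <- pmin(pert[[k]] + runif(1, 0, 0.1), 1)
    tot <- pert$cropland + pert$pasture + pert$urban
    if (any(tot > 1)) {
      sc <- ifelse(tot > 1, 1 / tot, 1)
      for (cl in names(pert)) pert[[cl]] <- pert[[cl]] * sc
    }
    a1 <- range_area(actual_range_field(sp, b, pert), areas)
    if (a1 > a0 + 1e-9) viol <- viol + 1L
  }
  expect_equal(viol, 0L)
})

test_that("the no-migration filter restricts to presently suitable cells", {
  sp <- sp2(eoo = c(1, 1))
  now <- bm2(c(1, 2), 2016)   # cell 2 unsuitable at present
  later <- bm2(c(1, 1), 2100) # both suitable in the future
  filt <- no_migration_filter(sp, now)
  expect_equal(filt$eoo_fraction, matrix(c(1, 0), 1, 2))
  # only the always-suitable cell contributes to the future range
  expect_equal(potential_range_field(filt, later), matrix(c(1, 0), 1, 2))
  # vacuous when present equals future suitability everywhere
  filt2 <- no_migration_filter(sp, later)
  expect_equal(filt2$eoo_fraction, sp$eoo_fraction)
  # present unsuitable everywhere -> zero future range
  none <- no_migration_filter(sp, bm2(c(2, 2), 2016))
  expect_equal(range_area(potential_range_field(none, later),
                          matrix(1, 1, 2)), 0)
  # subset property on a generated world
  w <- small_world()
  b_now <- w$biomes[[length(w$biomes)]]
  for (sp in w$species[1:6]) {
    f <- no_migration_filter(sp, b_now)
    expect_true(all(f$eoo_fraction <= sp$eoo_fraction + 1e-12))
  }
})

test_that("range series are constant under static inputs and flag exclusions", {
  yrs <- c(1850L, 1900L, 1950L)
  arr <- array(0, c(1, 2, 3, 3), dimnames = list(NULL, NULL,
               c("cropland", "pasture", "urban"), yrs))
  lu <- landuse_series(g12, yrs, list(baseline = arr))
  b <- list(bm2(c(1, 2), 1850))
  sp <- sp2(eoo = c(1, 0.5))
  rs <- compute_range_series(sp, b, lu, t0 = 1850)
  expect_equal(rs$A_potential_km2, rs$A_actual_km2)
  expect_equal(length(unique(round(rs$A_potential_km2, 6))), 1L)
  expect_false(attr(rs, "excluded"))
  # a species whose biome never occurs has zero baseline -> excluded
  sp0 <- sp2(biomes = 2L, eoo = c(1, 0))
  rs0 <- compute_range_series(sp0, b, lu, t0 = 1850)
  expect_true(attr(rs0, "excluded"))
  expect_equal(rs0$A_potential_km2, rep(0, 3))
  expect_error(compute_range_series(sp, b, lu, years = integer(0)), "empty")
})
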