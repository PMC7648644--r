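test_that("world generation is deterministic given the seed", {
  cfg <- world_config(seed = 99, resolution = 2, lat_min = -30, lat_max = 30,
                      lon_min = 0, lon_max = 40,
                      n_species = c(mammal = 5, bird = 5, amphibian = 5))
  w1 <- gen_world(cfg)
  w2 <- gen_world(cfg)
  expect_identical(w1$landuse$data, w2$landuse$data)
  expect_identical(lapply(w1$species, `[[`, "eoo_fraction"),
                   lapply(w2$species, `[[`, "eoo_fraction"))
  expect_identical(lapply(w1$biomes, `[[`, "codes"),
                   lapply(w2$biomes, `[[`, "codes"))
  # a different seed gives a different world
  w3 <- gen_world(world_config(seed = 100, resolution = 2, lat_min = -30,
                               lat_max = 30, lon_min = 0, lon_max = 40,
                               n_species = c(mammal = 5, bird = 5, amphibian = 5)))
  expect_false(identical(w1$landuse$data, w3$landuse$data))
})

test_that("zero uncertainty half-width collapses the variants", {
  w <- gen_world(world_config(seed = 12, resolution = 2, lat_min = -30,
                              lat_max = 30, lon_min = 0, lon_max = 40,
                              n_species = c(mammal = 2, bird = 2, amphibian = 2),
                              uncertainty_halfwidth = 0))
  expect_identical(w$landuse$data$lower, w$landuse$data$baseline)
  expect_identical(w$landuse$data$upper, w$landuse$data$baseline)
})

test_that("generated bundles satisfy every ingest invariant", {
  w <- small_world()
  lu <- w$landuse
  expect_true(all(lu$data$lower <= lu$data$baseline + 1e-12))
  expect_true(all(lu$data$baseline <= lu$data$upper + 1e-12))
  for (v in names(lu$data)) {
    a <- lu$data[[v]]
    expect_true(all(a >= 0 & a <= 1))
    tot <- a[, , 1, ] + a[, , 2, ] + a[, , 3, ]
    expect_true(all(tot <= 1 + 1e-9))
    # monotone non-decreasing trajectories towards the asymptote
    expect_true(all(apply(tot, c(1, 2), function(x) all(diff(x) >= -1e-12))))
  }
  # biome maps fully classified on the declared code list
  for (b in w$biomes) expect_true(all(b$codes %in% b$code_list))
  # species records pass their own validator and re-derive cleanly
  for (sp in w$species[1:5]) {
    expect_s3_class(species_record(sp$species_id, sp$group, sp$eoo_fraction,
                                   sp$suitable_biomes, sp$suitable_artificial,
                                   sp$grid), "species_record")
  }
})

test_that("the late-onset region peaks later and hosts smaller ranges", {
  w <- default_world()
  peak <- peak_conversion_time(w$landuse, t_max = 2016)
  trop <- peak[w$tropical_mask]
  extra <- peak[!w$tropical_mask]
  expect_gt(median(trop, na.rm = TRUE), median(extra, na.rm = TRUE))
  # construction guarantee: strictly later typical onset, by decades
  expect_gt(median(trop, na.rm = TRUE) - median(extra, na.rm = TRUE), 30)
  # tropical species draw smaller extents (log-uniform, scaled down)
  areas <- cell_areas(w$grid)
  sizes <- vapply(w$species, function(sp) sum(sp$eoo_fraction * areas), numeric(1))
  centroid_trop <- vapply(w$species, function(sp) {
    cc <- cell_centres(w$grid)
    lat <- matrix(cc$lat, w$grid$nlat, w$grid$nlon)
    sum(lat * sp$eoo_fraction) / sum(sp$eoo_fraction)
  }, numeric(1))
  in_trop <- abs(centroid_trop) < w$cfg$tropical_lat
  expect_lt(median(sizes[in_trop]), median(sizes[!in_trop]))
})

test_that("the toy biome classifier applies documented threshold rules", {
  g <- grid_spec(1, 0, 2, 0, 2)
  mk <- function(t, p) list(
    temperature = climate_field("temperature", 2000, g, array(t, c(2, 2, 12))),
    precipitation = climate_field("precipitation", 2000, g, array(p, c(2, 2, 12))))
  # uniform warm-wet climate -> single biome (tropical humid, code 1)
  cl <- mk(25, 120)
  b <- toy_biome_classify(cl$temperature, cl$precipitation)
  expect_true(all(b$codes == 1L))
  # exactly on the temperature threshold -> lower (temperate) band
  b2 <- toy_biome_classify(mk(18, 120)$temperature, mk(18, 120)$precipitation)
  expect_true(all(b2$codes == 3L))
  # exactly on the moisture threshold -> dry band
  b3 <- toy_biome_classify(mk(25, 60)$temperature, mk(25, 60)$precipitation)
  expect_true(all(b3$codes == 2L))
  # cold and dry -> code 6
  b4 <- toy_biome_classify(mk(0, 10)$temperature, mk(0, 10)$precipitation)
  expect_true(all(b4$codes == 6L))
})

test_that("warming shifts the tropical biome boundary poleward", {
  cfg <- world_config(seed = 1, resolution = 1, lat_min = -40, lat_max = 40,
                      lon_min = 0, lon_max = 10,
                      n_species = c(mammal = 1, bird = 1, amphibian = 1))
  b_early <- habitatrange:::toy_biomes_at(cfg, grid_spec(1, -40, 40, 0, 10), 1850)
  b_late <- habitatrange:::toy_biomes_at(cfg, grid_spec(1, -40, 40, 0, 10), 2016,
                                         warming_per_century = 3)
  # highest |latitude| of a tropical-band cell grows under warming; the
  # threshold latitude is analytic: T = 28 - 0.8|lat| + w crosses 18 at
  # |lat| = (10 + w) / 0.8
  cc <- cell_centres(grid_spec(1, -40, 40, 0, 10))
  lat_trop_early <- max(abs(cc$lat[rowSums(b_early$codes <= 2) > 0]))
  lat_trop_late <- max(abs(cc$lat[rowSums(b_late$codes <= 2) > 0]))
  expect_gt(lat_trop_late, lat_trop_early)
  w_late <- 3 * (2016 - 1900) / 100
  expect_lt(abs(lat_trop_early - 10 / 0.8), 1.1)       # centre spacing bound
  expect_lt(abs(lat_trop_late - (10 + w_late) / 0.8), 1.1)
})

test_that("median loss keeps falling while land use only grows", {
  # sign-convention sanity across seeds: with static biomes and monotone
  # conversion, every strict-mode trajectory is non-increasing (the retained
  # fraction is 1 - sum of unsuitable class fractions), so the median is too
  for (seed in c(2, 3)) {
    w <- gen_world(world_config(seed = seed, resolution = 2, lat_min = -30,
                                lat_max = 30, lon_min = 0, lon_max = 40,
                                n_species = c(mammal = 6, bird = 6, amphibian = 6),
                                warming_per_century = 0))
    res <- run_pipeline(w, mode = "strict")
    med <- res$percentiles[res$percentiles$percentile == 50, ]
    med <- med[order(med$year), ]
    expect_true(all(diff(med$value) <= 1e-6))
  }
})
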