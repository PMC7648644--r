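test_that("relative range change follows the baseline-ratio formula", {
  expect_equal(range_change(100, 100), 0)
  expect_equal(range_change(0, 100), -100)
  expect_equal(range_change(150, 100), 50)
  expect_true(is.na(range_change(10, 0)))       # zero baseline -> excluded
  expect_equal(range_change(c(50, 200), c(100, 100)), c(-50, 100))
  # climate-only variant: same formula on potential areas
  expect_equal(climate_only_change(100, 100), 0)
  expect_equal(climate_only_change(50, 100), -50)
})

# independent sort-and-rank oracle for linear-interpolation percentiles
oracle_quantile <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

test_that("percentile curves match a brute-force sorted-rank oracle", {
  tab <- data.frame(year = 2000, delta_pct = rep(-20, 5))
  expect_true(all(percentile_curves(tab)$value == -20))
  tab3 <- data.frame(year = 2000, delta_pct = c(-90, -50, -10))
  expect_equal(percentile_curves(tab3, 50)$value, -50)
  # 101 evenly spaced values from -100 to 0: 10th percentile by oracle
  v <- seq(-100, 0, by = 1)
  tab101 <- data.frame(year = 2016, delta_pct = v)
  expect_equal(percentile_curves(tab101, 10)$value, oracle_quantile(v, 0.1))
  # random inputs of size <= 50, every decile, against the oracle
  set.seed(21)
  for (rep in 1:40) {
    x <- rnorm(sample(1:50, 1), sd = 30)
    got <- percentile_curves(data.frame(year = 1, delta_pct = x))$value
    want <- vapply(seq(0.1, 0.9, 0.1), oracle_quantile, numeric(1), x = x)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # NA (excluded) entries are dropped, empty input errors
  tabna <- data.frame(year = 2000, delta_pct = c(-50, NA))
  expect_equal(percentile_curves(tabna, 50)$value, -50)
  expect_error(percentile_curves(data.frame(year = 1, delta_pct = NA_real_)),
               "no included species")
})

test_that("critical-loss shares use a strict threshold and group coherently", {
  expect_equal(critical_loss_fraction(c(-10, -20, -30)), 0)
  expect_equal(critical_loss_fraction(c(-60, -70, -10, -20)), 0.5)
  # boundary exactly at -50 is not critical (strict inequality)
  expect_equal(critical_loss_fraction(c(-50, -50.0001)), 0.5)
  # excluded species are ignored
  expect_equal(critical_loss_fraction(c(-60, NA)), 1)
  # grouped shares: within-group and of-all normalisations
  d <- c(-60, -70, -10, -80, -20, -30)
  g <- c("trop", "trop", "trop", "temp", "temp", "temp")
  out <- critical_loss_fraction(d, groups = g)
  expect_equal(out$share_within[out$group == "trop"], 2 / 3)
  expect_equal(out$share_within[out$group == "temp"], 1 / 3)
  # of-all shares, summed over groups, equal the overall fraction exactly
  expect_equal(sum(out$share_of_all), critical_loss_fraction(d))
  # count-weighted within-group shares also recover the overall fraction
  expect_equal(sum(out$share_within * out$n) / sum(out$n),
               critical_loss_fraction(d))
})

test_that("the primary mega-biome is the largest area-share group", {
  g <- grid_spec(1, 0, 1, 0, 3)  # one row, three equal-area cells
  mega <- data.frame(biome = 1:4,
                     mega_biome = c("a_trop", "b_temp", "b_temp", "c_bor"))
  mk <- function(eoo, biomes) species_record("s", "bird", matrix(eoo, 1, 3),
                                             biomes, character(0), g)
  b <- biome_map(matrix(c(1, 2, 3), 1, 3), 1850, 1:4)
  # single-biome range -> that biome's mega-biome
  expect_equal(primary_mega_biome(mk(c(1, 0, 0), 1:4), b, mega), "a_trop")
  # 2/3 of the area in mega-biome b_temp (biomes 2+3) vs 1/3 in a_trop
  expect_equal(primary_mega_biome(mk(c(1, 1, 1), 1:4), b, mega), "b_temp")
  # exact tie (equal areas in one row) -> lexicographically lowest label
  b2 <- biome_map(matrix(c(1, 2, 1), 1, 3), 1850, 1:4)
  expect_equal(primary_mega_biome(mk(c(0, 1, 1), 1:4), b2, mega), "a_trop")
  expect_error(primary_mega_biome(mk(c(1, 0, 0), 4L), b, mega), "excluded")
})

test_that("marginal losses are flat for linear curves and flagged otherwise", {
  yrs <- 2000:2004
  area <- c(0, 10, 20, 30, 40) * 1e6
  loss <- c(0, 2, 4, 6, 8)      # linear in converted area
  out <- marginal_loss_curve(yrs, loss, area)
  expect_equal(out$marginal_loss_per_km2[-1], rep(2 / 10e6, 4))
  # convex curve -> increasing marginal losses
  out2 <- marginal_loss_curve(yrs, c(0, 1, 3, 6, 10), area)
  expect_true(all(diff(out2$marginal_loss_per_km2[-1]) > 0))
  # zero conversion throughout -> no defined marginal values
  out3 <- marginal_loss_curve(yrs, rep(0, 5), rep(0, 5))
  expect_true(all(is.na(out3$marginal_loss_per_km2)))
  expect_error(marginal_loss_curve(yrs, loss[-1], area), "mismatch")
})

test_that("local mean range-size maps average the species present per cell", {
  areas <- matrix(1, 1, 4)
  f1 <- matrix(c(1, 1, 0, 0), 1, 4)    # size 2
  f2 <- matrix(c(1, 0, 0, 0), 1, 4)    # size 1
  out <- local_mean_range_map(list(f1, f2), areas)
  expect_equal(out[1, 1], 1.5)          # both present -> (2 + 1) / 2
  expect_equal(out[1, 2], 2)            # only species 1
  expect_true(is.na(out[1, 3]))         # empty cell flagged
  # one species everywhere -> constant map equal to its global size
  out1 <- local_mean_range_map(list(matrix(0.5, 1, 4)), areas)
  expect_true(all(out1 == 2))
  # a cluster of small-ranged species drags its region's mean down
  smalls <- lapply(1:3, function(i) matrix(c(1, 0, 0, 0), 1, 4))
  big <- matrix(c(0, 0, 1, 1), 1, 4)
  out2 <- local_mean_range_map(c(smalls, list(big)), areas)
  expect_lt(out2[1, 1], out2[1, 3])
})

test_that("bootstrap percentile summaries are degenerate-safe and reproducible", {
  # all-equal input: SD exactly zero at every percentile
  out <- bootstrap_percentiles(rep(-20, 50), n_boot = 200, seed = 1)
  expect_true(all(out$sd == 0))
  expect_true(all(out$mean == -20))
  # same seed -> identical output; different seed -> different draws
  x <- rnorm(100)
  a <- bootstrap_percentiles(x, n_boot = 100, seed = 5)
  b <- bootstrap_percentiles(x, n_boot = 100, seed = 5)
  c <- bootstrap_percentiles(x, n_boot = 100, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(bootstrap_percentiles(numeric(0), seed = 1), "empty")
  expect_error(bootstrap_percentiles(x, n_boot = 10), "seed")
  # the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(bootstrap_percentiles(x, n_boot = 10, seed = 9))
  expect_identical(runif(1), before)
})

test_that("bootstrap recentres the median within its own standard error", {
  set.seed(31)
  x <- rnorm(1000)
  direct <- median(x)
  out <- bootstrap_percentiles(x, percentiles = 50, n_boot = 10000, seed = 77)
  # the bootstrap SD estimates the sampling SE of the median; the bootstrap
  # mean must sit well within it (3 SE) of the direct estimate
  expect_lt(abs(out$mean - direct), 3 * out$sd)
})

test_that("multi-model aggregation uses the sample SD and flags n = 1", {
  same <- scenario_aggregate(list(c(-10, -20), c(-10, -20), c(-10, -20)))
  expect_true(all(same$sd == 0))
  one_t <- scenario_aggregate(matrix(c(-10, -20, -30), 1, 3))
  expect_equal(one_t$mean, -20)
  expect_equal(one_t$sd, 10)            # sample (n-1) formula
  single <- scenario_aggregate(matrix(c(-5, -6), 2, 1), years = c(2050, 2100))
  expect_equal(single$mean, c(-5, -6))
  expect_true(all(is.na(single$sd)))
  expect_equal(single$year, c(2050, 2100))
  expect_error(scenario_aggregate(list(1:3, 1:4)), "length")
})
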