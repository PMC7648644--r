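# Shared fixtures, built once per test run and memoised.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# The study-condition synthetic world (generator defaults).
default_world <- function() memo("world", gen_world(world_config(seed = 20260920L)))

# A small, fast world for property tests that loop.
small_world <- function() memo("small", gen_world(world_config(
  seed = 11L, resolution = 2, lat_min = -30, lat_max = 30,
  lon_min = 0, lon_max = 40,
  n_species = c(mammal = 8, bird = 8, amphibian = 8))))

# Random convex polygon (points on a noisy circle, sorted by angle -> convex
# hull via chull so the ring is guaranteed simple).
random_convex_ring <- function(cx, cy, r_max) {
  n <- sample(4:10, 1)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 0.3, 1) * r_max
  pts <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  pts[grDevices::chull(pts), , drop = FALSE]
}

# Independent brute-force oracle: tests every fine-cell centre one at a time
# with sp-free scalar geometry (crossing-number with explicit edge test),
# written without reference to the package's vectorised implementation.
oracle_coverage <- function(ring, fine_grid, coarse_grid, factor = 6L) {
  cc <- cell_centres(fine_grid)
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- nrow(ring)
  pip <- function(px, py) {
    on <- FALSE; inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
      d <- abs((px - x1) * (y2 - y1) - (py - y1) * (x2 - x1))
      if (d < 1e-12 && px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
          py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12) on <- TRUE
      if ((y1 > py) != (y2 > py) && px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
        inside <- !inside
      j <- i
    }
    inside || on
  }
  flags <- matrix(0, fine_grid$nlat, fine_grid$nlon)
  for (i in seq_len(fine_grid$nlat))
    for (k in seq_len(fine_grid$nlon))
      flags[i, k] <- as.numeric(pip(cc$lon[k], cc$lat[i]))
  nr <- fine_grid$nlat %/% factor
  nc <- fine_grid$nlon %/% factor
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (k in seq_len(nc))
      out[i, k] <- sum(flags[(i - 1) * factor + 1:factor,
                             (k - 1) * factor + 1:factor]) / factor^2
  out
}
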