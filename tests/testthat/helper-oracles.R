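# Shared fixtures and independent oracles for the test suite.

# Small, fast local-design configuration for unit tests.
tiny_local_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(design = "local", n_segments = 30L, coastline_length_km = 3,
         n_surveys = 12L, true_radius_km = 0.8,
         raster_spec = list(margin_km = 1.5), seed = seed),
    list(...))
  do.call(sim_config, args)
}

tiny_regional_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(design = "regional", n_segments = 8L, coastline_length_km = 12,
         true_radius_km = 1.5, wrack_radius_km = 0.8,
         raster_spec = list(margin_km = 1.5), seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Brute-force buffer aggregation: O(pixels x segments x radii) double loop.
brute_force_aggregate <- function(mean_raster, geometry, radii) {
  n <- nrow(geometry)
  out <- matrix(0, n, length(radii),
                dimnames = list(geometry$segment_id,
                                format(radii, trim = TRUE)))
  for (i in seq_len(n)) {
    d <- sqrt((mean_raster$x_km - geometry$x_km[i])^2 +
                (mean_raster$y_km - geometry$y_km[i])^2)
    for (j in seq_along(radii)) {
      out[i, j] <- sum(mean_raster$mean_biomass[d <= radii[j]])
    }
  }
  out
}

# Random small raster + geometry instance for oracle comparisons.
random_instance <- function(seed, n_pix_side = 20, n_seg = 6, n_rad = 8) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(n_pix_side) * 0.1,
                   y = seq_len(n_pix_side) * 0.1)
  mr <- list(x_km = g$x, y_km = g$y,
             mean_biomass = runif(nrow(g), 0, 10), quarters = "2020-Q1")
  xs <- sort(runif(n_seg, 0, n_pix_side * 0.1))
  xs <- xs + seq_len(n_seg) * 1e-3     # strict alongshore order
  geom <- coast_geometry(xs, rep(0, n_seg),
                         runif(n_seg, 90, 230), segment_length_km = NA)
  radii <- sort(runif(n_rad, 0.05, n_pix_side * 0.15))
  list(mean_raster = mr, geometry = geom, radii = radii)
}

# Straight-line geometry without randomness.
line_geometry <- function(n, seg_len = 0.1, orientation = 180) {
  coast_geometry((seq_len(n) - 0.5) * seg_len, rep(0, n),
                 rep(orientation, n), segment_length_km = seg_len)
}

# Single-quarter raster from explicit pixel coordinates/values.
point_raster <- function(x, y, biomass) {
  canopy_raster(x, y, matrix(biomass, ncol = 1), "2020-Q1")
}
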