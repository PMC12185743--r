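test_that("local generator produces the stated design shapes", {
  gen <- generate_local_dataset(sim_config("local", seed = 4))
  expect_equal(nrow(gen$geometry), 250)
  expect_equal(attr(gen$geometry, "segment_length_km"), 0.1)
  expect_equal(attr(gen$geometry, "coastline_length_km"), 25)
  expect_equal(nrow(gen$surveys), 250 * 66)
  expect_true(all(gen$surveys$plant_count >= 0))
  expect_true(all(gen$surveys$dry_width_m >= 0 &
                    gen$surveys$dry_width_m <= 127))
  expect_true(all(gen$geometry$orientation_deg >= 87 &
                    gen$geometry$orientation_deg <= 237))
  expect_true(all(gen$raster$biomass >= 0))
  expect_setequal(unique(gen$waves$window), c("all", SEASONS))
})

test_that("generators are deterministic given the seed", {
  g1 <- generate_local_dataset(tiny_local_config(seed = 5))
  g2 <- generate_local_dataset(tiny_local_config(seed = 5))
  g3 <- generate_local_dataset(tiny_local_config(seed = 6))
  expect_identical(g1$surveys, g2$surveys)
  expect_identical(g1$raster$biomass, g2$raster$biomass)
  expect_false(identical(g1$surveys$plant_count, g3$surveys$plant_count))
  # and at the level of written CSV text
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_survey_csv(g1$surveys, p1); write_survey_csv(g2$surveys, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_local_dataset(tiny_local_config()))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless identity: y equals the R* buffer sum exactly", {
  cfg <- tiny_local_config(
    seed = 2,
    beta = c(intercept = 0, biomass = 1, width = 0,
             cos_orientation = 0, sin_orientation = 0, wave = 0),
    arma_sd = 0, noise_sd = 0)
  gen <- generate_local_dataset(cfg)
  b_star <- aggregate_biomass(temporal_mean_biomass(gen$raster),
                              gen$geometry, cfg$true_radius_km)[, 1]
  resp <- seasonal_mean_response(gen$surveys, "all")
  expect_equal(unname(resp[names(b_star)]), unname(b_star),
               tolerance = 1e-8)
  # regressing y on the R* buffer sum returns beta exactly
  f <- fit_gls(as.numeric(resp[names(b_star)]),
               cbind(1, biomass = b_star), mode = "ols")
  expect_equal(unname(f$beta), c(0, 1), tolerance = 1e-8)
})

test_that("invalid configurations are rejected naming the bound", {
  expect_error(sim_config("local", phi = 1.01), "phi")
  expect_error(sim_config("local", theta = -1), "theta")
  expect_error(sim_config("local", noise_sd = -1), "noise_sd")
  expect_error(sim_config("local", n_segments = 2), "n_segments")
  expect_error(sim_config("local", raster_spec = list(pixel_km = 0)),
               "pixel")
  expect_error(generate_local_dataset(sim_config("regional")), "local")
})

test_that("regional generator: 24 sites, 3 replicates, wrack response", {
  gen <- generate_regional_dataset(sim_config("regional", seed = 3))
  expect_equal(nrow(gen$geometry), 24)
  expect_equal(nrow(gen$surveys), 24 * 3)
  expect_true("wrack_cover" %in% names(gen$surveys))
  expect_true(all(gen$surveys$wrack_cover >= 0))
  expect_true(all(table(gen$surveys$segment_id) == 3))
  expect_equal(length(gen$raster$quarters), 4)
  expect_lt(gen$truth$wrack_radius_km, gen$truth$true_radius_km)
})

test_that("no-signal wrack: scan statistic flat in radius", {
  cfg <- tiny_regional_config(
    seed = 8,
    wrack_beta = c(intercept = 1, biomass = 0, width = 0,
                   cos_orientation = 0, sin_orientation = 0, wave = 0),
    wrack_noise_sd = 1e-4)
  gen <- generate_regional_dataset(cfg)
  wr <- seasonal_mean_response(gen$surveys, "all", "wrack_cover")
  bbr <- aggregate_biomass(temporal_mean_biomass(gen$raster),
                           gen$geometry, radius_grid(0.5, 2, 0.5))
  sc <- scan_radii(wr, bbr, method = "ols")
  expect_true(all(sc$statistic < 0.5))   # no radius explains much
})
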