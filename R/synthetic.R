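#' Quarter label of a date
#'
#' @param date `Date` vector.
#' @return Labels like `"2016-Q1"`.
#' @export
quarter_label <- function(date) {
  m <- as.integer(format(date, "%m"))
  sprintf("%s-Q%d", format(date, "%Y"), (m - 1L) %/% 3L + 1L)
}

#' Simulation configuration for the synthetic coastline
#'
#' Houses the planted connectivity radius R*, the true driver coefficients,
#' the ARMA(1,1) alongshore noise parameters, and the survey/raster layout.
#' Defaults encode the local design: a straight 25 km coastline of 250
#' contiguous 100 m segments surveyed monthly for 66 months, with 30 m
#' raster pixels in an offshore strip. The regional design (`design =
#' "regional"`) is 24 irregularly spaced sites along ~100 km with three
#' replicate surveys and a wrack-cover response with its own coefficients
#' and its own (smaller) R*.
#'
#' @param design `"local"` or `"regional"`.
#' @param true_radius_km Planted connectivity radius R* (km) for the plant
#'   count response.
#' @param beta Named coefficients `(intercept, biomass, width,
#'   cos_orientation, sin_orientation, wave)` generating the plant response.
#' @param phi,theta ARMA(1,1) parameters of the alongshore noise field, each
#'   in (-1, 1).
#' @param arma_sd Marginal SD of the alongshore ARMA(1,1) field eta
#'   (response units); 0 switches the field off.
#' @param noise_sd SD of the independent per-survey noise e; 0 switches it
#'   off.
#' @param n_segments,n_surveys Design size.
#' @param start_month First survey month (`Date`).
#' @param coastline_length_km Coastline span (km).
#' @param orientation_range Envelope (degrees) the generated shore-normal
#'   orientations are confined to.
#' @param width_winter_m,width_summer_m Seasonal mean dry-beach widths (m)
#'   anchoring the seasonal width cycle (winter minimum, summer maximum).
#' @param curvature_km Amplitude of an optional sinusoidal coastline
#'   curvature (0 = straight line).
#' @param wrack_radius_km,wrack_beta,wrack_noise_sd Regional wrack-cover
#'   response: its own R*, coefficients, and replicate noise SD.
#' @param raster_spec List: `pixel_km`, `strip_km` (offshore distance range
#'   of the reef patches), `margin_km` (raster extension beyond the
#'   coastline ends so end-segment buffers are not empty),
#'   `patch_density_per_km`, `patch_width_km`, `amp_meanlog`, `amp_sdlog`,
#'   `quarter_jitter_sdlog` (quarter-to-quarter lognormal amplitude jitter).
#' @param seed Integer seed; every random draw derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(design = c("local", "regional"),
                       true_radius_km = NULL,
                       beta = NULL,
                       phi = 0.6, theta = 0.2,
                       arma_sd = NULL, noise_sd = NULL,
                       n_segments = NULL, n_surveys = NULL,
                       start_month = NULL,
                       coastline_length_km = NULL,
                       orientation_range = NULL,
                       width_winter_m = 1.7, width_summer_m = 7.7,
                       curvature_km = 0,
                       wrack_radius_km = 2.2,
                       wrack_beta = NULL,
                       wrack_noise_sd = 0.28,
                       raster_spec = list(),
                       seed = 1L) {
  design <- match.arg(design)
  local <- design == "local"
  cfg <- list(
    design = design,
    true_radius_km = true_radius_km %||% (if (local) 2.9 else 5.6),
    beta = beta %||% (if (local) {
      c(intercept = 100, biomass = 1.1e-3, width = 0.2,
        cos_orientation = 1.5, sin_orientation = 1.0, wave = 3.0)
    } else {
      c(intercept = 10, biomass = 1.53e-3, width = 0,
        cos_orientation = 0, sin_orientation = 0, wave = 0)
    }),
    phi = phi, theta = theta,
    arma_sd = arma_sd %||% (if (local) 20 else 0),
    noise_sd = noise_sd %||% (if (local) 12 else 10),
    n_segments = n_segments %||% (if (local) 250L else 24L),
    n_surveys = n_surveys %||% (if (local) 66L else 3L),
    start_month = start_month %||%
      (if (local) as.Date("2015-08-01") else as.Date("2017-10-01")),
    coastline_length_km = coastline_length_km %||% (if (local) 25 else 100),
    orientation_range = orientation_range %||%
      (if (local) c(87, 237) else c(104, 241)),
    width_winter_m = width_winter_m, width_summer_m = width_summer_m,
    curvature_km = curvature_km,
    wrack_radius_km = wrack_radius_km,
    wrack_beta = wrack_beta %||%
      c(intercept = 0.07, biomass = 1.4e-4, width = 0,
        cos_orientation = 0, sin_orientation = -0.08, wave = 0),
    wrack_noise_sd = wrack_noise_sd,
    raster_spec = utils::modifyList(list(
      pixel_km = 0.03, strip_km = c(0.1, 1.5), margin_km = 10,
      patch_density_per_km = 1.6, patch_width_km = 0.15,
      amp_meanlog = log(3), amp_sdlog = 0.6,
      quarter_jitter_sdlog = 0.3), raster_spec),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_arma_params(cfg$phi, cfg$theta)
  if (!(cfg$arma_sd >= 0)) stop("arma_sd must be >= 0")
  if (!(cfg$noise_sd >= 0)) stop("noise_sd must be >= 0")
  if (cfg$n_segments < 3) stop("n_segments must be >= 3")
  if (cfg$n_surveys < 1) stop("n_surveys must be >= 1")
  if (!(cfg$raster_spec$pixel_km > 0)) stop("raster pixel size must be > 0")
  if (!(cfg$true_radius_km > 0)) stop("true_radius_km must be > 0")
  beta_names <- c("intercept", "biomass", "width", "cos_orientation",
                  "sin_orientation", "wave")
  if (!identical(names(cfg$beta), beta_names)) {
    stop("beta must be named (", paste(beta_names, collapse = ", "), ")")
  }
  invisible(cfg)
}

# smooth alongshore profile in [lo, hi]: shifted sinusoids + AR-smoothed noise
smooth_profile <- function(pos, lo, hi, wavelength_km, rough_sd = 0.08) {
  ph <- runif(2, 0, 2 * pi)
  base <- 0.6 * sin(2 * pi * pos / wavelength_km + ph[1]) +
    0.4 * sin(2 * pi * pos / (wavelength_km / 2.7) + ph[2])
  rough <- as.numeric(stats::filter(rnorm(length(pos), sd = rough_sd), 0.9,
                                    method = "recursive"))
  z <- base + rough
  z <- (z - min(z)) / max(max(z) - min(z), 1e-12)   # to [0, 1]
  lo + z * (hi - lo)
}

make_geometry <- function(cfg) {
  n <- cfg$n_segments
  L <- cfg$coastline_length_km
  if (cfg$design == "local") {
    seg_len <- L / n
    x <- (seq_len(n) - 0.5) * seg_len
  } else {
    seg_len <- NA_real_
    # irregular but ordered site positions with a minimum spacing
    x <- sort(runif(n, 0, L))
    min_gap <- L / (4 * n)
    x <- x + seq_len(n) * min_gap        # enforce strict ordering/spacing
    x <- (x - min(x)) / (max(x) - min(x)) * L
    x[1] <- 0; x[n] <- L
  }
  y <- if (cfg$curvature_km > 0) {
    cfg$curvature_km * sin(2 * pi * x / L)
  } else rep(0, length(x))
  orient <- smooth_profile(x, cfg$orientation_range[1],
                           cfg$orientation_range[2], wavelength_km = L / 2.2)
  coast_geometry(x, y, orient, segment_length_km = seg_len)
}

# Gaussian reef patches in an offshore strip; per-quarter lognormal
# amplitude jitter gives quarter-to-quarter variation around a fixed
# spatial pattern.
make_raster <- function(cfg, quarters) {
  rs <- cfg$raster_spec
  L <- cfg$coastline_length_km
  xg <- seq(-rs$margin_km, L + rs$margin_km, by = rs$pixel_km)
  yg <- seq(rs$strip_km[1], rs$strip_km[2], by = rs$pixel_km)
  grid <- expand.grid(x_km = xg, y_km = yg, KEEP.OUT.ATTRS = FALSE)
  n_patch <- max(3L, round(rs$patch_density_per_km * (L + 2 * rs$margin_km)))
  pcx <- runif(n_patch, -rs$margin_km, L + rs$margin_km)
  pcy <- runif(n_patch, rs$strip_km[1], rs$strip_km[2])
  amp <- rlnorm(n_patch, rs$amp_meanlog, rs$amp_sdlog)
  w2 <- rs$patch_width_km^2
  nq <- length(quarters)
  jit <- matrix(rlnorm(n_patch * nq, -rs$quarter_jitter_sdlog^2 / 2,
                       rs$quarter_jitter_sdlog), n_patch, nq)
  # sparse accumulation: each patch only touches pixels within 4 widths
  biomass <- matrix(0, nrow(grid), nq)
  for (k in seq_len(n_patch)) {
    xin <- which(abs(xg - pcx[k]) < 4 * rs$patch_width_km)
    if (!length(xin)) next
    cells <- as.vector(outer(xin, (seq_along(yg) - 1L) * length(xg), "+"))
    d2 <- (grid$x_km[cells] - pcx[k])^2 + (grid$y_km[cells] - pcy[k])^2
    near <- d2 < 16 * w2
    cells <- cells[near]
    kern <- exp(-d2[near] / (2 * w2)) * amp[k]
    for (q in seq_len(nq)) {
      biomass[cells, q] <- biomass[cells, q] + kern * jit[k, q]
    }
  }
  canopy_raster(grid$x_km, grid$y_km, biomass, quarters,
                pixel_km = rs$pixel_km)
}

make_waves <- function(cfg, geometry, windows) {
  pos <- alongshore_position(geometry$x_km, geometry$y_km)
  base <- smooth_profile(pos, 0.8, 1.6,
                         wavelength_km = cfg$coastline_length_km / 1.7)
  season_factor <- c(all = 1, winter = 1.25, spring = 1.05, summer = 0.85,
                     fall = 1.0, plants = 1.1, wrack = 0.95)
  do.call(rbind, lapply(windows, function(w) {
    hs <- base * season_factor[[w]] *
      exp(rnorm(length(base), 0, 0.03))
    data.frame(segment_id = geometry$segment_id, window = w,
               mean_hs_m = pmax(hs, 0.05), stringsAsFactors = FALSE)
  }))
}

# seasonal dry-beach width cycle: summer max, winter min, truncated at 0
survey_widths <- function(cfg, months, n_seg) {
  mid <- (cfg$width_winter_m + cfg$width_summer_m) / 2
  amp <- (cfg$width_summer_m - cfg$width_winter_m) / 2
  seg_off <- rnorm(n_seg, 0, 2.5)
  mnum <- as.integer(format(months, "%m"))
  out <- matrix(0, n_seg, length(months))
  for (j in seq_along(months)) {
    w <- mid + seg_off + amp * cos(2 * pi * (mnum[j] - 8) / 12) +
      rnorm(n_seg, 0, 1)
    out[, j] <- pmin(pmax(w, 0), 127)
  }
  out
}

#' Generate the synthetic local-design dataset
#'
#' Draws a seeded dataset in the exact shapes of the local design: monthly
#' plant counts and dry-beach widths per 100 m segment, a quarterly canopy
#' raster, and per-window wave means. The plant response is
#' `y(seg, month) = beta . x(seg, month) + eta_month(seg) + e`, where the
#' biomass covariate is the buffer sum at exactly R* computed with the same
#' aggregation operator as the analysis ([aggregate_biomass()]), `eta` is a
#' mean-zero ARMA(1,1) field over the alongshore segment order (redrawn each
#' month), `e` is independent Gaussian month noise, and counts are floored
#' at 0.
#'
#' @param config A [sim_config()] with `design = "local"`.
#' @return List with `geometry`, `raster`, `surveys`, `waves`, `truth`
#'   (R*, beta, phi, theta, seed), and the `config`.
#' @export
generate_local_dataset <- function(config = sim_config("local")) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (config$design != "local") stop("config$design must be 'local'")
  with_seed(config$seed, {
    months <- seq(config$start_month, by = "month",
                  length.out = config$n_surveys)
    quarters <- unique(quarter_label(months))
    geometry <- make_geometry(config)
    raster <- make_raster(config, quarters)
    waves <- make_waves(config, geometry, c("all", SEASONS))
    n <- config$n_segments
    b_star <- aggregate_biomass(temporal_mean_biomass(raster), geometry,
                                radii = config$true_radius_km)[, 1L]
    oc <- orientation_components(geometry$orientation_deg)
    hs <- waves$mean_hs_m[waves$window == "all"]
    widths <- survey_widths(config, months, n)
    bt <- config$beta
    fixed <- bt[["intercept"]] + bt[["biomass"]] * b_star +
      bt[["cos_orientation"]] * oc$cos_orientation +
      bt[["sin_orientation"]] * oc$sin_orientation +
      bt[["wave"]] * hs
    rows <- vector("list", length(months))
    for (j in seq_along(months)) {
      eta <- if (config$arma_sd > 0) {
        simulate_arma11(n, config$phi, config$theta, sd = config$arma_sd)
      } else rep(0, n)
      e <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else
        rep(0, n)
      yy <- fixed + bt[["width"]] * widths[, j] + eta + e
      rows[[j]] <- data.frame(
        segment_id = geometry$segment_id,
        survey_date = months[j],
        plant_count = pmax(yy, 0),
        dry_width_m = widths[, j],
        stringsAsFactors = FALSE)
    }
    surveys <- do.call(rbind, rows)
    surveys <- surveys[base::order(surveys$segment_id,
                                   surveys$survey_date), ]
    rownames(surveys) <- NULL
    validate_survey_table(surveys)
    list(geometry = geometry, raster = raster, surveys = surveys,
         waves = waves,
         truth = list(design = "local",
                      true_radius_km = config$true_radius_km,
                      beta = config$beta, phi = config$phi,
                      theta = config$theta, seed = config$seed),
         config = config)
  })
}

#' Generate the synthetic regional-design dataset
#'
#' 24 irregularly spaced beach sites along ~100 km, three replicate surveys
#' per site. Plant counts are expressed per km of beach; a wrack-cover
#' response is added with its own coefficient set and its own planted
#' radius (default 2.2 km, smaller than the plant R* of 5.6 km). Responses
#' are floored at 0.
#'
#' @param config A [sim_config()] with `design = "regional"`.
#' @return As [generate_local_dataset()]; `truth` additionally carries
#'   `wrack_radius_km` and `wrack_beta`, and `surveys` a `wrack_cover`
#'   column.
#' @export
generate_regional_dataset <- function(config = sim_config("regional")) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (config$design != "regional") stop("config$design must be 'regional'")
  with_seed(config$seed, {
    months <- seq(config$start_month, by = "2 months",
                  length.out = config$n_surveys)
    # canopy averaged over the year preceding sampling: four quarters
    qdates <- seq(config$start_month - 365, by = "3 months", length.out = 4)
    quarters <- unique(quarter_label(qdates))
    geometry <- make_geometry(config)
    raster <- make_raster(config, quarters)
    waves <- make_waves(config, geometry, c("all", "plants", "wrack"))
    n <- config$n_segments
    mean_r <- temporal_mean_biomass(raster)
    b_plant <- aggregate_biomass(mean_r, geometry,
                                 radii = config$true_radius_km)[, 1L]
    b_wrack <- aggregate_biomass(mean_r, geometry,
                                 radii = config$wrack_radius_km)[, 1L]
    oc <- orientation_components(geometry$orientation_deg)
    hs_p <- waves$mean_hs_m[waves$window == "plants"]
    hs_w <- waves$mean_hs_m[waves$window == "wrack"]
    widths <- survey_widths(config, months, n)
    widths <- pmin(pmax(widths + 12, 4.5), 32)   # regional beaches all dry
    bt <- config$beta; bw <- config$wrack_beta
    fixed_p <- bt[["intercept"]] + bt[["biomass"]] * b_plant +
      bt[["cos_orientation"]] * oc$cos_orientation +
      bt[["sin_orientation"]] * oc$sin_orientation + bt[["wave"]] * hs_p
    fixed_w <- bw[["intercept"]] + bw[["biomass"]] * b_wrack +
      bw[["cos_orientation"]] * oc$cos_orientation +
      bw[["sin_orientation"]] * oc$sin_orientation + bw[["wave"]] * hs_w
    # site-level noise shared by the replicates; replicate noise on top
    eta_p <- if (config$arma_sd > 0) {
      simulate_arma11(n, config$phi, config$theta, sd = config$arma_sd)
    } else rep(0, n)
    rows <- vector("list", length(months))
    for (j in seq_along(months)) {
      yp <- fixed_p + eta_p + rnorm(n, 0, config$noise_sd) +
        bt[["width"]] * widths[, j]
      yw <- fixed_w + rnorm(n, 0, config$wrack_noise_sd) +
        bw[["width"]] * widths[, j]
      rows[[j]] <- data.frame(
        segment_id = geometry$segment_id,
        survey_date = months[j],
        plant_count = pmax(yp, 0),
        dry_width_m = widths[, j],
        wrack_cover = pmax(yw, 0),
        stringsAsFactors = FALSE)
    }
    surveys <- do.call(rbind, rows)
    surveys <- surveys[base::order(surveys$segment_id,
                                   surveys$survey_date), ]
    rownames(surveys) <- NULL
    validate_survey_table(surveys, require_wrack = TRUE)
    list(geometry = geometry, raster = raster, surveys = surveys,
         waves = waves,
         truth = list(design = "regional",
                      true_radius_km = config$true_radius_km,
                      beta = config$beta, phi = config$phi,
                      theta = config$theta,
                      wrack_radius_km = config$wrack_radius_km,
                      wrack_beta = config$wrack_beta,
                      seed = config$seed),
         config = config)
  })
}
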