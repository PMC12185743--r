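#' Run configuration for the end-to-end pipeline
#'
#' Validated before any stage runs and echoed verbatim into the output
#' manifest.
#'
#' @param design `"local"` or `"regional"`.
#' @param rmin,rmax,rstep Radius grid (km).
#' @param seasons Seasonal scans to run in addition to the full record
#'   (local design only); `character(0)` to skip.
#' @param mode Model mode: `"gls"` (local default) or `"ols"` (regional
#'   default).
#' @param all_subsets Use the all-subsets candidate set for the drivers
#'   stage.
#' @param seed Integer seed for the simulate stage.
#' @param sim Optional [sim_config()] overriding the design default.
#' @return A validated `run_config` list.
#' @export
run_config <- function(design = c("local", "regional"),
                       rmin = 0.1, rmax = 10.0, rstep = 0.1,
                       seasons = if (design[1] == "local") SEASONS else
                         character(0),
                       mode = NULL, all_subsets = FALSE, seed = 1L,
                       sim = NULL) {
  design <- match.arg(design)
  if (!(rstep > 0)) stop("rstep must be > 0")
  if (!(rmin > 0) || !(rmax >= rmin)) stop("need 0 < rmin <= rmax")
  if (length(seasons) && !all(seasons %in% SEASONS)) {
    stop("unknown season(s): ",
         paste(setdiff(seasons, SEASONS), collapse = ", "))
  }
  mode <- mode %||% (if (design == "local") "gls" else "ols")
  mode <- match.arg(mode, c("gls", "ols"))
  if (is.null(seed)) stop("seed is required when simulation is requested")
  sim <- sim %||% sim_config(design, seed = seed)
  structure(list(design = design, rmin = rmin, rmax = rmax, rstep = rstep,
                 seasons = seasons, mode = mode, all_subsets = all_subsets,
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

#' Run the full pipeline: simulate, aggregate, scan, drivers
#'
#' Chains the stages on a seeded synthetic dataset, writes every stage
#' output under `out_dir` (CSV/JSON), and writes a reproducibility manifest
#' (`manifest.json`: config echo, package version, per-file MD5 checksums,
#' stage log) last. On stage failure, partial outputs are removed and the
#' error is rethrown.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message("[wrackscale] ", line)
    log <<- c(log, line)
  }
  emit <- function(fname, writer) {
    path <- file.path(out_dir, fname)
    writer(path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  # simulate
  t0 <- Sys.time()
  gen <- if (config$design == "local") {
    generate_local_dataset(config$sim)
  } else {
    generate_regional_dataset(config$sim)
  }
  note("simulate: design=%s seed=%d segments=%d surveys=%d",
       config$design, config$seed, nrow(gen$geometry),
       nrow(gen$surveys))
  emit("segments.csv", function(p) write_segments_csv(gen$geometry, p))
  emit("surveys.csv", function(p) write_survey_csv(gen$surveys, p))
  emit("waves.csv", function(p) write_waves_csv(gen$waves, p))
  emit("raster.csv", function(p) write_raster_csv(gen$raster, p))
  emit("truth.json", function(p) {
    jsonlite::write_json(gen$truth, p, auto_unbox = TRUE, digits = NA)
  })

  # aggregate
  radii <- radius_grid(config$rmin, config$rmax, config$rstep)
  mr <- temporal_mean_biomass(gen$raster)
  bbr <- aggregate_biomass(mr, gen$geometry, radii)
  note("aggregate: %d segments x %d radii", nrow(bbr), ncol(bbr))
  emit("biomass_by_radius.csv", function(p) {
    long <- data.frame(segment_id = rep(rownames(bbr), times = ncol(bbr)),
                       radius_km = rep(radii, each = nrow(bbr)),
                       biomass_sum = as.vector(bbr))
    write.csv(long, p, row.names = FALSE, quote = FALSE)
  })

  # scan (full record + seasons)
  resp <- seasonal_mean_response(gen$surveys, "all")
  scans <- list(all = scan_radii(resp, bbr, method = config$mode))
  if (length(config$seasons)) {
    scans <- c(scans, seasonal_scan(gen$surveys, gen$raster, gen$geometry,
                                    radii, method = config$mode,
                                    seasons = config$seasons))
  }
  if (config$design == "regional") {
    wr <- seasonal_mean_response(gen$surveys, "all", "wrack_cover")
    scans$wrack <- scan_radii(wr, bbr, method = config$mode)
  }
  for (nm in names(scans)) {
    emit(sprintf("scan_%s_%s.csv", config$design, nm),
         function(p) write_scan_csv(scans[[nm]], p))
    note("scan[%s]: optimum %.1f km (stat %.3f)", nm,
         attr(scans[[nm]], "optimal_radius_km"),
         attr(scans[[nm]], "optimal_statistic"))
  }
  emit("scan_summary.json", function(p) {
    jsonlite::write_json(lapply(scans, function(s) {
      list(optimal_radius_km = attr(s, "optimal_radius_km"),
           statistic = attr(s, "optimal_statistic"),
           significant = attr(s, "optimal_significant"),
           method = attr(s, "method"), season = attr(s, "season"))
    }), p, auto_unbox = TRUE, digits = NA)
  })

  # drivers at the selected optimum of the full-record scan
  cands <- candidate_set(config$all_subsets)
  design_tab <- build_design_table(gen$surveys, gen$geometry, gen$waves)
  ropt <- attr(scans$all, "optimal_radius_km")
  design_tab$biomass <-
    bbr[design_tab$segment_id, which(radii == ropt)]
  drv <- fit_drivers(design_tab, mode = config$mode, candidates = cands)
  note("drivers: selected '%s' (AIC %.2f) at %.1f km", drv$selected,
       drv$aic[[drv$selected]], ropt)
  emit(sprintf("drivers_%s_all.csv", config$design), function(p) {
    tab <- as.data.frame(drv$table)
    tab <- cbind(predictor = rownames(tab), tab)
    write.csv(tab, p, row.names = FALSE, quote = FALSE)
  })
  emit("drivers_fit.json", function(p) write_fit_json(drv$fit, p))
  emit("drivers_aic.json", function(p) {
    jsonlite::write_json(as.list(drv$aic), p, auto_unbox = TRUE,
                         digits = NA)
  })

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest <- list(
    config = unclass_recursive(config),
    package_version = as.character(utils::packageVersion("wrackscale")),
    files = lapply(stats::setNames(written, basename(written)),
                   function(p) unname(tools::md5sum(p))),
    log = log,
    elapsed_sec = elapsed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_recursive)
    attributes(x) <- list(names = names(x))
    x
  } else if (inherits(x, "Date")) {
    format(x, "%Y-%m-%d")
  } else {
    if (!is.null(attributes(x))) {
      attributes(x) <- list(names = names(x))
    }
    x
  }
}
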