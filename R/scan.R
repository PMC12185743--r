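#' Radius scan: fit the response at every candidate radius
#'
#' Fits one single-predictor model (intercept + buffer-summed biomass at
#' that radius) per candidate radius and records the fit statistic — the
#' overall GLS F-value (`method = "gls"`) or the OLS r-squared
#' (`method = "ols"`) — with its p-value. Radii whose biomass column is
#' constant (undefined slope) are skipped with a warning and excluded from
#' the optimum.
#'
#' @param response Named per-segment mean response (names = segment ids).
#' @param biomass A [aggregate_biomass()] matrix.
#' @param method `"gls"` (F statistic) or `"ols"` (r-squared).
#' @param order Alongshore order index for the segments in `response`;
#'   default = the row order of `biomass` restricted to `response`.
#' @param season Season tag stored on the result (bookkeeping only).
#' @return A `scan_result`: data.frame (`radius_km`, `statistic`,
#'   `p_value`, `significant`) plus attributes `optimal_radius_km`,
#'   `optimal_statistic`, `optimal_significant`, `method`, `season`.
#' @export
scan_radii <- function(response, biomass, method = c("gls", "ols"),
                       order = NULL, season = "all") {
  method <- match.arg(method)
  ids <- names(response)
  if (is.null(ids)) stop("response must be named by segment id")
  miss <- setdiff(ids, rownames(biomass))
  if (length(miss)) {
    stop("segment id(s) absent from biomass matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  keep <- !is.na(response)
  ids <- ids[keep]
  y <- as.numeric(response[keep])
  if (length(y) < 3L) stop("need >= 3 segments with data")
  B <- biomass[ids, , drop = FALSE]
  radii <- attr(biomass, "radii_km")
  if (is.null(order)) order <- seq_along(y)
  rows <- lapply(seq_along(radii), function(j) {
    bcol <- B[, j]
    if (sd(bcol) == 0) {
      warning("radius ", radii[j], " km: constant biomass column, skipped",
              call. = FALSE)
      return(data.frame(radius_km = radii[j], statistic = NA_real_,
                        p_value = NA_real_, significant = NA))
    }
    fit <- fit_gls(y, cbind(`(Intercept)` = 1, biomass = bcol),
                   mode = method, order = order)
    stat <- if (method == "gls") fit$f_value else fit$r2
    data.frame(radius_km = radii[j], statistic = stat,
               p_value = fit$f_p_value,
               significant = fit$f_p_value < 0.05)
  })
  df <- do.call(rbind, rows)
  opt <- select_optimum(df)
  structure(df, class = c("scan_result", "data.frame"),
            optimal_radius_km = opt$optimal_radius_km,
            optimal_statistic = opt$optimal_statistic,
            optimal_significant = opt$significant,
            method = method, season = season)
}

#' Select the optimal radius from a scan
#'
#' The radius with the maximum fit statistic; ties break to the smallest
#' radius (parsimony). If no radius is significant at p < 0.05 the maximum
#' is still returned, flagged `significant = FALSE` — non-significant
#' optima are reported, not suppressed. Failed radii (`NA` statistic) are
#' excluded from the argmax.
#'
#' @param scan Data frame with `radius_km`, `statistic`, `p_value`.
#' @return List: `optimal_radius_km`, `optimal_statistic`, `p_value`,
#'   `significant`.
#' @export
select_optimum <- function(scan) {
  if (NROW(scan) == 0L) stop("empty scan: no radii fitted")
  ok <- !is.na(scan$statistic)
  if (!any(ok)) stop("no radius produced a valid fit")
  sc <- scan[ok, , drop = FALSE]
  sc <- sc[base::order(sc$radius_km), , drop = FALSE]
  i <- which.max(sc$statistic)   # first maximum = smallest radius on ties
  list(optimal_radius_km = sc$radius_km[i],
       optimal_statistic = sc$statistic[i],
       p_value = sc$p_value[i],
       significant = isTRUE(sc$p_value[i] < 0.05))
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "scan_result (%s, season %s): %d radii, optimum %.1f km (stat %.3f%s)\n",
    attr(x, "method"), attr(x, "season"), nrow(x),
    attr(x, "optimal_radius_km"), attr(x, "optimal_statistic"),
    if (isTRUE(attr(x, "optimal_significant"))) "" else ", not significant"))
  invisible(x)
}

#' Seasonal radius scans
#'
#' Re-runs the radius scan per season: responses are per-season segment
#' means and the biomass predictor is re-aggregated from season-matched
#' calendar quarters (winter Q1, spring Q2, summer Q3, fall Q4). Seasons
#' with no surveys are skipped with a warning.
#'
#' @param surveys Segment survey table.
#' @param raster A [canopy_raster()].
#' @param geometry A [coast_geometry()].
#' @param radii Radius grid (km).
#' @param method `"gls"` or `"ols"`.
#' @param response Response column.
#' @param seasons Seasons to scan (default all four).
#' @return Named list of `scan_result`, one per season with data.
#' @export
seasonal_scan <- function(surveys, raster, geometry, radii = radius_grid(),
                          method = "gls", response = "plant_count",
                          seasons = SEASONS) {
  months_present <- unique(month_season(as.Date(surveys$survey_date)))
  out <- list()
  for (s in seasons) {
    if (!s %in% months_present) {
      warning("season '", s, "' has no surveys; skipped", call. = FALSE)
      next
    }
    qnum <- match(s, SEASONS)
    qsel <- raster$quarters[as.integer(sub(".*-Q", "", raster$quarters)) ==
                              qnum]
    if (length(qsel) == 0L) {
      warning("season '", s, "' has no matching raster quarters; skipped",
              call. = FALSE)
      next
    }
    resp <- suppressWarnings(seasonal_mean_response(surveys, s, response))
    if (sum(!is.na(resp)) < 3L) {
      warning("season '", s, "' has < 3 segments with data; skipped",
              call. = FALSE)
      next
    }
    mr <- temporal_mean_biomass(raster, qsel)
    bbr <- aggregate_biomass(mr, geometry, radii)
    ord <- match(names(resp)[!is.na(resp)], geometry$segment_id)
    out[[s]] <- scan_radii(resp[!is.na(resp)], bbr, method = method,
                           order = rank(ord), season = s)
  }
  out
}
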