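#' Map calendar months to seasons
#'
#' Jan-Mar winter, Apr-Jun spring, Jul-Sep summer, Oct-Dec fall — a total
#' partition of the 12 months, aligned with calendar quarters Q1-Q4.
#'
#' @param month Integer month(s) 1-12, or `Date`(s).
#' @return Character vector in `c("winter", "spring", "summer", "fall")`.
#' @export
month_season <- function(month) {
  if (inherits(month, "Date")) month <- as.integer(format(month, "%m"))
  stopifnot(all(month %in% 1:12))
  c("winter", "spring", "summer", "fall")[(month - 1L) %/% 3L + 1L]
}

#' Seasons recognised by the seasonal analyses
#' @export
SEASONS <- c("winter", "spring", "summer", "fall")

# calendar quarter number carrying each season (aligned partition)
season_quarter <- function(season) {
  match(match.arg(season, SEASONS), SEASONS)
}

#' Per-segment mean response, overall or by season
#'
#' Arithmetic mean of a response column across the surveys falling in the
#' selected season (or all surveys). Segments with no survey in the season
#' are returned as `NA` with a warning and should be excluded from modeling.
#'
#' @param surveys A segment survey table (long format with `segment_id`,
#'   `survey_date`, and the response column).
#' @param season One of `"all"`, `"winter"`, `"spring"`, `"summer"`,
#'   `"fall"`.
#' @param response Response column name (default `"plant_count"`).
#' @return Named numeric vector of per-segment means (names = segment ids,
#'   in first-appearance order).
#' @export
seasonal_mean_response <- function(surveys, season = "all",
                                   response = "plant_count") {
  validate_survey_table(surveys)
  if (!response %in% names(surveys)) {
    stop("response column not found: ", response)
  }
  season <- match.arg(season, c("all", SEASONS))
  ids <- unique(surveys$segment_id)
  sel <- if (season == "all") rep(TRUE, nrow(surveys)) else {
    month_season(as.Date(surveys$survey_date)) == season
  }
  sub <- surveys[sel, , drop = FALSE]
  means <- tapply(sub[[response]], factor(sub$segment_id, levels = ids),
                  mean)
  out <- as.numeric(means)
  names(out) <- ids
  if (anyNA(out)) {
    warning(sum(is.na(out)), " segment(s) have no survey in season '",
            season, "'; returned as NA", call. = FALSE)
  }
  out
}

#' Circular orientation components
#'
#' Decomposes a shore-normal compass bearing (degrees) into its east-west
#' (sine) and north-south (cosine) components for use as linear predictors.
#'
#' @param orientation_deg Bearings in degrees.
#' @return Data frame with `sin_orientation` and `cos_orientation`.
#' @examples
#' orientation_components(180) # sin 0, cos -1
#' @export
orientation_components <- function(orientation_deg) {
  stopifnot(all(is.finite(orientation_deg)))
  rad <- orientation_deg * pi / 180
  data.frame(sin_orientation = sin(rad), cos_orientation = cos(rad))
}

#' Assemble the regression-ready design table
#'
#' One row per segment: mean response, mean dry beach width, orientation
#' sine/cosine, mean significant wave height, and the alongshore order
#' index. The biomass column (at a chosen radius) is joined separately from
#' a [aggregate_biomass()] matrix.
#'
#' @param surveys Segment survey table.
#' @param geometry A [coast_geometry()].
#' @param waves Wave table (`segment_id`, `window`, `mean_hs_m`).
#' @param season `"all"` or a season; seasonal means for the response and
#'   width use the season's surveys, and the wave window of the same name is
#'   used when present (falling back to `"all"`).
#' @param response Response column name.
#' @return A `data.frame` with columns `segment_id`, `mean_response`,
#'   `mean_width_m`, `sin_orientation`, `cos_orientation`, `mean_hs_m`,
#'   `order` (alongshore index). Segments lacking data in the season are
#'   dropped (with the warning from [seasonal_mean_response()]).
#' @export
build_design_table <- function(surveys, geometry, waves, season = "all",
                               response = "plant_count") {
  stopifnot(inherits(geometry, "coast_geometry"))
  resp <- seasonal_mean_response(surveys, season, response)
  width <- seasonal_mean_response(surveys, season, "dry_width_m")
  oc <- orientation_components(geometry$orientation_deg)
  win <- if (season %in% waves$window) season else "all"
  wv <- waves[waves$window == win, , drop = FALSE]
  hs <- wv$mean_hs_m[match(geometry$segment_id, wv$segment_id)]
  out <- data.frame(
    segment_id = geometry$segment_id,
    mean_response = as.numeric(resp[geometry$segment_id]),
    mean_width_m = as.numeric(width[geometry$segment_id]),
    sin_orientation = oc$sin_orientation,
    cos_orientation = oc$cos_orientation,
    mean_hs_m = hs,
    order = seq_len(nrow(geometry)),
    stringsAsFactors = FALSE
  )
  out[!is.na(out$mean_response), , drop = FALSE]
}
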