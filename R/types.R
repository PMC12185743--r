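#' Coastline geometry of survey segments
#'
#' Planar (km) centers of alongshore-ordered beach segments with their
#' shore-normal orientations.
#'
#' @param x_km,y_km Segment center coordinates (km), ordered alongshore.
#' @param orientation_deg Shore-normal compass bearing per segment, in
#'   `[0, 360)`.
#' @param segment_length_km Alongshore segment length (km); consecutive
#'   center spacing must equal it (checked along the alongshore coordinate
#'   when the coastline is straight; for curved coastlines the arc spacing is
#'   taken as given).
#' @param segment_id Optional ids; default `seg_001`, ...
#' @return A `coast_geometry` data frame (segment_id, x_km, y_km,
#'   orientation_deg) with attributes `segment_length_km` and
#'   `coastline_length_km`.
#' @export
coast_geometry <- function(x_km, y_km, orientation_deg, segment_length_km,
                           segment_id = NULL) {
  n <- length(x_km)
  stopifnot(length(y_km) == n, length(orientation_deg) == n, n >= 1)
  if (any(orientation_deg < 0 | orientation_deg >= 360)) {
    stop("orientation_deg must lie in [0, 360)")
  }
  pos <- alongshore_position(x_km, y_km)
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("segment centers must be strictly ordered alongshore")
  }
  # regular designs (local): consecutive spacing must equal segment_length
  if (!is.na(segment_length_km) && n > 1L &&
      any(abs(diff(pos) - segment_length_km) > 1e-9)) {
    stop("consecutive center spacing must equal segment_length_km ",
         "within 1e-9")
  }
  if (is.null(segment_id)) {
    segment_id <- sprintf("seg_%03d", seq_len(n))
  }
  out <- data.frame(segment_id = as.character(segment_id),
                    x_km = x_km, y_km = y_km,
                    orientation_deg = orientation_deg,
                    stringsAsFactors = FALSE)
  attr(out, "segment_length_km") <- segment_length_km
  attr(out, "coastline_length_km") <-
    if (is.na(segment_length_km)) diff(range(pos)) else n * segment_length_km
  class(out) <- c("coast_geometry", "data.frame")
  out
}

# cumulative alongshore arc position of ordered centers
alongshore_position <- function(x_km, y_km) {
  n <- length(x_km)
  if (n == 1L) return(0)
  step <- sqrt(diff(x_km)^2 + diff(y_km)^2)
  cumsum(c(0, step))
}

#' Gridded kelp canopy biomass
#'
#' Regular-grid pixel centers (planar km) with nonnegative biomass per pixel
#' per quarter.
#'
#' @param x_km,y_km Pixel center coordinates (km).
#' @param biomass Numeric matrix, pixels x quarters, nonnegative.
#' @param quarters Ordered quarter labels (e.g. `"2016-Q1"`), one per column.
#' @param pixel_km Grid spacing in km (default 0.03 = 30 m pixels).
#' @return A `canopy_raster` list.
#' @export
canopy_raster <- function(x_km, y_km, biomass, quarters,
                          pixel_km = 0.03) {
  biomass <- as.matrix(biomass)
  stopifnot(length(x_km) == nrow(biomass), length(y_km) == nrow(biomass),
            length(quarters) == ncol(biomass), pixel_km > 0)
  if (any(biomass < 0)) stop("biomass must be nonnegative everywhere")
  colnames(biomass) <- quarters
  structure(list(x_km = x_km, y_km = y_km, biomass = biomass,
                 quarters = as.character(quarters), pixel_km = pixel_km),
            class = "canopy_raster")
}

#' @export
print.canopy_raster <- function(x, ...) {
  cat(sprintf("canopy_raster: %d pixels x %d quarters (%.0f m pixels)\n",
              length(x$x_km), length(x$quarters), x$pixel_km * 1000))
  invisible(x)
}

# Validate a long-format segment survey table.
validate_survey_table <- function(df, require_wrack = FALSE) {
  need <- c("segment_id", "survey_date", "plant_count", "dry_width_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("survey table missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- duplicated(paste(df$segment_id, df$survey_date))
  if (any(dup)) {
    stop("duplicate (segment_id, survey_date) at row(s) ",
         paste(which(dup), collapse = ", "))
  }
  if (any(df$plant_count < 0)) {
    stop("negative plant_count at row(s) ",
         paste(which(df$plant_count < 0), collapse = ", "))
  }
  if (any(df$dry_width_m < 0)) {
    stop("negative dry_width_m at row(s) ",
         paste(which(df$dry_width_m < 0), collapse = ", "))
  }
  if (require_wrack && !"wrack_cover" %in% names(df)) {
    stop("survey table missing wrack_cover column")
  }
  if ("wrack_cover" %in% names(df) && any(df$wrack_cover < 0, na.rm = TRUE)) {
    stop("negative wrack_cover at row(s) ",
         paste(which(df$wrack_cover < 0), collapse = ", "))
  }
  invisible(df)
}
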