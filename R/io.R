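#' Read / write the pipeline's CSV schemas
#'
#' Comma-separated, UTF-8, mandatory header, '.' decimal; dates ISO-8601;
#' coordinates in kilometers. Readers enforce the table invariants on load
#' and report offending rows.
#'
#' @param path File path.
#' @return The typed table.
#' @name wrackscale_io
NULL

# Serialize doubles at 17 significant digits so a write/read round trip
# reproduces the exact binary values (boundary pixels on a buffer radius
# would otherwise flip under default 15-digit text).
format_doubles <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' @rdname wrackscale_io
#' @export
read_survey_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_survey_table(df)
  d <- as.Date(df$survey_date)
  if (anyNA(d)) {
    stop("unparseable ISO-8601 survey_date at row(s) ",
         paste(which(is.na(d)), collapse = ", "), " in ", path)
  }
  df$survey_date <- d
  df
}

#' @rdname wrackscale_io
#' @param surveys Survey table to write.
#' @export
write_survey_csv <- function(surveys, path) {
  out <- surveys
  out$survey_date <- format(as.Date(out$survey_date), "%Y-%m-%d")
  write.csv(format_doubles(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname wrackscale_io
#' @export
read_segments_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "x_km", "y_km", "orientation_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("segments file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  seg_len <- attr(df, "segment_length_km") %||% NA_real_
  coast_geometry(df$x_km, df$y_km, df$orientation_deg,
                 segment_length_km = seg_len, segment_id = df$segment_id)
}

#' @rdname wrackscale_io
#' @param geometry Geometry to write.
#' @export
write_segments_csv <- function(geometry, path) {
  write.csv(format_doubles(as.data.frame(geometry)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname wrackscale_io
#' @param waves Wave table to write.
#' @export
write_waves_csv <- function(waves, path) {
  write.csv(format_doubles(waves), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname wrackscale_io
#' @export
read_waves_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "window", "mean_hs_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("waves file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(df$mean_hs_m <= 0)) {
    stop("non-positive mean_hs_m at row(s) ",
         paste(which(df$mean_hs_m <= 0), collapse = ", "))
  }
  dup <- duplicated(df[, c("segment_id", "window")])
  if (any(dup)) {
    stop("duplicate (segment_id, window) at row(s) ",
         paste(which(dup), collapse = ", "))
  }
  df
}

#' @rdname wrackscale_io
#' @param raster A [canopy_raster()] (long CSV: x_km, y_km, quarter,
#'   biomass).
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "canopy_raster"))
  long <- data.frame(
    x_km = rep(raster$x_km, times = length(raster$quarters)),
    y_km = rep(raster$y_km, times = length(raster$quarters)),
    quarter = rep(raster$quarters, each = length(raster$x_km)),
    biomass = as.vector(raster$biomass))
  write.csv(format_doubles(long), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname wrackscale_io
#' @param pixel_km Grid spacing of the raster being read (km).
#' @export
read_raster_csv <- function(path, pixel_km = 0.03) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_km", "y_km", "quarter", "biomass")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("raster file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(df$biomass < 0)) {
    stop("negative biomass at row(s) ",
         paste(which(df$biomass < 0), collapse = ", "))
  }
  quarters <- unique(df$quarter)
  key <- paste(df$x_km, df$y_km)
  pix <- unique(key)
  bm <- matrix(0, length(pix), length(quarters))
  for (j in seq_along(quarters)) {
    sub <- df[df$quarter == quarters[j], ]
    bm[match(paste(sub$x_km, sub$y_km), pix), j] <- sub$biomass
  }
  first <- match(pix, key)
  canopy_raster(df$x_km[first], df$y_km[first], bm, quarters,
                pixel_km = pixel_km)
}

#' @rdname wrackscale_io
#' @param scan A `scan_result`.
#' @export
write_scan_csv <- function(scan, path) {
  write.csv(as.data.frame(scan), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fit summary to JSON
#'
#' Coefficient table (estimate, SE, t-value, p-value per predictor) plus
#' fit statistics, mirroring the drivers-table layout.
#'
#' @param fit A `gls_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "gls_fit"))
  obj <- list(
    mode = fit$mode,
    coefficients = data.frame(predictor = names(fit$beta),
                              estimate = as.numeric(fit$beta),
                              se = as.numeric(fit$se),
                              t_value = as.numeric(fit$t_values),
                              p_value = as.numeric(fit$p_values)),
    arma = fit$arma, sigma2 = fit$sigma2, loglik = fit$loglik,
    aic = fit$aic, f_value = fit$f_value, f_p_value = fit$f_p_value,
    r2 = fit$r2, n = fit$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
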