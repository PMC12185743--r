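#' Candidate radius grid
#'
#' Default is the standard scan grid: 0.1 km to 10.0 km at 0.1 km
#' increments (100 radii).
#'
#' @param rmin,rmax,rstep Grid bounds and step in km.
#' @return Strictly increasing positive numeric vector of radii (km).
#' @export
radius_grid <- function(rmin = 0.1, rmax = 10.0, rstep = 0.1) {
  if (!(rstep > 0)) stop("rstep must be > 0")
  if (!(rmin > 0) || rmax < rmin) stop("need 0 < rmin <= rmax")
  r <- seq(rmin, rmax, by = rstep)
  round(r, 10)
}

#' Per-pixel temporal mean of canopy biomass
#'
#' Arithmetic mean of each pixel's biomass over the selected quarters
#' (the "mean" in summed-mean-within-buffer: temporal mean first, spatial
#' sum second).
#'
#' @param raster A [canopy_raster()].
#' @param quarters Character subset of `raster$quarters`; `NULL` means all.
#' @return List with `x_km`, `y_km`, `mean_biomass`, `quarters` used.
#' @export
temporal_mean_biomass <- function(raster, quarters = NULL) {
  stopifnot(inherits(raster, "canopy_raster"))
  if (is.null(quarters)) quarters <- raster$quarters
  if (length(quarters) == 0L) stop("quarter selection is empty")
  bad <- setdiff(quarters, raster$quarters)
  if (length(bad)) {
    stop("unknown quarter(s): ", paste(bad, collapse = ", "))
  }
  sel <- raster$quarters %in% quarters
  list(x_km = raster$x_km, y_km = raster$y_km,
       mean_biomass = rowMeans(raster$biomass[, sel, drop = FALSE]),
       quarters = raster$quarters[sel])
}

#' Buffer-summed mean canopy biomass by radius
#'
#' For every segment center and every candidate radius, sums the per-pixel
#' temporal-mean biomass over all pixels whose center lies within Euclidean
#' distance r (closed disk, `<=`) of the segment center. Rows are
#' non-decreasing in radius by construction (cumulative over distance bins).
#'
#' @param mean_raster Output of [temporal_mean_biomass()].
#' @param geometry A [coast_geometry()].
#' @param radii A radius grid from [radius_grid()] (strictly increasing, km).
#' @return A `biomass_by_radius` matrix, segments x radii, with segment ids
#'   as rownames and radii (km) as colnames; provenance in attributes.
#' @export
aggregate_biomass <- function(mean_raster, geometry, radii = radius_grid()) {
  stopifnot(inherits(geometry, "coast_geometry"))
  if (is.unsorted(radii, strictly = TRUE) || any(radii <= 0)) {
    stop("radii must be strictly increasing and positive")
  }
  px <- mean_raster$x_km
  py <- mean_raster$y_km
  b <- mean_raster$mean_biomass
  if (length(px) != length(b) || length(py) != length(b)) {
    stop("raster/geometry frame mismatch: coordinate and biomass lengths differ")
  }
  n <- nrow(geometry)
  m <- length(radii)
  B <- matrix(0, n, m, dimnames = list(geometry$segment_id,
                                       format(radii, trim = TRUE)))
  # pixels sorted by x so each segment only sees its +-rmax alongshore band
  ordx <- base::order(px)
  pxs <- px[ordx]; pys <- py[ordx]; bs <- b[ordx]
  rmax <- radii[m]
  for (i in seq_len(n)) {
    cx <- geometry$x_km[i]; cy <- geometry$y_km[i]
    lo <- findInterval(cx - rmax, pxs, left.open = TRUE) + 1L
    hi <- findInterval(cx + rmax, pxs)
    if (lo > hi) next
    win <- lo:hi
    d <- sqrt((pxs[win] - cx)^2 + (pys[win] - cy)^2)
    # index of the smallest radius whose closed disk contains the pixel
    j <- findInterval(d, radii, left.open = TRUE) + 1L
    keep <- j <= m
    if (any(keep)) {
      acc <- numeric(m)
      s <- rowsum(bs[win][keep], j[keep])
      acc[as.integer(rownames(s))] <- s
      B[i, ] <- cumsum(acc)
    }
  }
  structure(B, class = c("biomass_by_radius", "matrix", "array"),
            radii_km = radii,
            quarters = mean_raster$quarters,
            pixel_km = attr(mean_raster, "pixel_km"))
}

#' @export
print.biomass_by_radius <- function(x, ...) {
  cat(sprintf("biomass_by_radius: %d segments x %d radii (%.1f-%.1f km)\n",
              nrow(x), ncol(x), min(attr(x, "radii_km")),
              max(attr(x, "radii_km"))))
  invisible(x)
}
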