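#' Default candidate predictor sets for the drivers model
#'
#' Every candidate contains the intercept and the biomass term. The default
#' pair — the full model and the full model without the wave-height term —
#' covers the two selection outcomes the drivers analysis distinguishes.
#' `all_subsets = TRUE` instead enumerates every subset of
#' (width, cos, sin, wave) on top of intercept + biomass.
#'
#' @param all_subsets Enumerate all biomass-anchored subsets instead.
#' @return Named list of character vectors of predictor names.
#' @export
candidate_set <- function(all_subsets = FALSE) {
  base <- c("biomass", "mean_width_m", "cos_orientation", "sin_orientation")
  if (!all_subsets) {
    return(list(full = c(base, "mean_hs_m"), no_wave = base))
  }
  opt <- c("mean_width_m", "cos_orientation", "sin_orientation", "mean_hs_m")
  subs <- unlist(lapply(0:length(opt), function(k) {
    utils::combn(opt, k, simplify = FALSE)
  }), recursive = FALSE)
  out <- lapply(subs, function(s) c("biomass", s))
  names(out) <- vapply(out, function(s) paste(s, collapse = "+"), "")
  out
}

validate_candidates <- function(candidates) {
  if (length(candidates) == 0L) stop("candidate set must be nonempty")
  ok <- vapply(candidates, function(s) "biomass" %in% s, TRUE)
  if (!all(ok)) {
    stop("every candidate must contain the biomass term; offending: ",
         paste(names(candidates)[!ok], collapse = ", "))
  }
  invisible(candidates)
}

#' Fit the multi-predictor drivers-of-deposition models
#'
#' Fits each candidate predictor subset (intercept + biomass always
#' included) by [fit_gls()] and selects the candidate with minimum AIC
#' (ties break to the candidate with fewer predictors, then first listed).
#'
#' @param design A [build_design_table()] data frame with a `biomass`
#'   column already joined (biomass at the selected optimal radius).
#' @param mode `"gls"` or `"ols"`.
#' @param candidates A [candidate_set()].
#' @param response Column of `design` used as the response
#'   (default `mean_response`).
#' @return A `drivers_fit`: `selected` (candidate name), `aic` (named, per
#'   candidate), `fits` (per-candidate `gls_fit`), `fit` (the selected one),
#'   and `table` (the selected fit's coefficient table).
#' @export
fit_drivers <- function(design, mode = c("gls", "ols"),
                        candidates = candidate_set(),
                        response = "mean_response") {
  mode <- match.arg(mode)
  validate_candidates(candidates)
  if (!"biomass" %in% names(design)) {
    stop("design table must contain a `biomass` column ",
         "(join from aggregate_biomass at the optimal radius)")
  }
  need <- unique(unlist(candidates))
  miss <- setdiff(c(response, need), names(design))
  if (length(miss)) {
    stop("design table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(design[, c(response, need)])) {
    stop("design table has missing values in model columns")
  }
  y <- design[[response]]
  ord <- design$order %||% seq_len(nrow(design))
  fits <- lapply(candidates, function(preds) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(design[, preds, drop = FALSE]))
    fit_gls(y, X, mode = mode, order = rank(ord))
  })
  aic <- vapply(fits, `[[`, 0, "aic")
  npred <- vapply(candidates, length, 0L)
  sel_order <- base::order(aic, npred, seq_along(aic))
  selected <- names(candidates)[sel_order[1L]]
  structure(list(selected = selected, aic = aic, fits = fits,
                 fit = fits[[selected]],
                 table = coef_table(fits[[selected]]),
                 mode = mode),
            class = "drivers_fit")
}

#' @export
print.drivers_fit <- function(x, ...) {
  cat("drivers_fit: AIC per candidate\n")
  print(round(x$aic, 2))
  cat("selected:", x$selected, "\n\n")
  print(x$fit)
  invisible(x)
}

#' Direction of the fitted orientation effect
#'
#' Evaluates the fitted orientation surface
#' `beta_cos * cos(d) + beta_sin * sin(d)` over compass directions and
#' reports the most- and least-favored bearings.
#'
#' @param fit A `drivers_fit` or `gls_fit` containing both orientation
#'   components.
#' @param directions_deg Bearings to evaluate (default the five southerly
#'   compass points 90, 135, 180, 225, 270).
#' @return List: `directions_deg`, `effect`, `max_deg`, `min_deg`.
#' @export
direction_of_effect <- function(fit,
                                directions_deg = c(90, 135, 180, 225, 270)) {
  if (inherits(fit, "drivers_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "gls_fit"))
  b <- fit$beta
  if (!all(c("cos_orientation", "sin_orientation") %in% names(b))) {
    stop("fit lacks orientation components (cos_orientation, sin_orientation)")
  }
  rad <- directions_deg * pi / 180
  eff <- b[["cos_orientation"]] * cos(rad) + b[["sin_orientation"]] * sin(rad)
  list(directions_deg = directions_deg, effect = as.numeric(eff),
       max_deg = directions_deg[which.max(eff)],
       min_deg = directions_deg[which.min(eff)])
}
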