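# wrackscale

Scale-of-effect analysis of kelp forest → sandy beach subsidies.

Sandy-beach food webs run on drift kelp (wrack) exported from nearshore
giant kelp forests. The question this package answers is *how local* that
connection is: within what radius of a beach segment does offshore kelp
canopy biomass best predict kelp deposition on the sand? It is written
for coastal and landscape ecologists who have (a) beach survey tables
(plant counts or wrack cover per segment per survey), (b) a gridded kelp
canopy biomass raster (e.g., 30 m Landsat-derived pixels per quarter),
and (c) per-site wave climate summaries — or who want to study the
estimator itself on synthetic coastlines with known ground truth.

## The method

For each beach segment *i* and candidate radius *r* (default 0.1–10 km
by 0.1 km), compute the buffer sum
B(i, r) = Σ over pixels within distance r of segment i's center of the
pixel's temporal-mean biomass, then fit per radius the single-predictor
model

    y_i = β0 + β1 B(i, r) + ε_i,   cor(ε_i, ε_j) = ρ(|i − j|)

where ρ is the ARMA(1,1) autocorrelation function of the alongshore
segment order, ρ(1) = (1+φθ)(φ+θ)/(1+2φθ+θ²), ρ(k) = φ ρ(k−1). The
(φ, θ) are estimated by profile maximum likelihood (Levinson–Durbin
whitening, Nelder–Mead with fixed multistarts). The optimal radius is
the one maximizing the model's overall F (GLS, local design) or r²
(OLS, regional design). At that radius a multi-predictor "drivers"
model adds dry beach width, sin/cos of the shore-normal orientation,
and mean significant wave height, with AIC-based candidate selection.
Seasonal variants stratify both the response means and the raster
quarters.

A seeded synthetic-coastline generator (`generate_local_dataset`,
`generate_regional_dataset`) plants a known connectivity radius R*,
known coefficients, and ARMA(1,1) alongshore noise in the exact shapes
of a 25 km / 250-segment monthly design and a 24-site / ~100 km
regional design, so estimator behavior (radius recovery, coefficient
bias, interval coverage, AIC selection) is testable end to end. See
`vignettes/wrackscale-methods.Rmd` for model details and stated-world
choices.

## Worked example

```r
library(wrackscale)
gen  <- generate_local_dataset(sim_config("local", seed = 1))
bbr  <- aggregate_biomass(temporal_mean_biomass(gen$raster),
                          gen$geometry, radius_grid())
resp <- seasonal_mean_response(gen$surveys, "all")
scan <- scan_radii(resp, bbr, method = "gls")
print(scan)
#> scan_result (gls, season all): 100 radii, optimum 3.0 km (stat 8.804)

radii <- attr(bbr, "radii_km")
dt <- build_design_table(gen$surveys, gen$geometry, gen$waves)
dt$biomass <- bbr[dt$segment_id,
                  which(radii == attr(scan, "optimal_radius_km"))]
drv <- fit_drivers(dt, mode = "gls")
print(drv)
#> drivers_fit: AIC per candidate
#>    full no_wave
#> 1169.54 1169.32
#> selected: no_wave
#>
#> GLS fit (n = 250)
#> ARMA(1,1) correlation: phi = 0.6734, theta = -0.3095
#>                 Estimate     SE t-value p-value
#> (Intercept)     102.6928 1.3145 78.1210  0.0000
#> biomass           0.0010 0.0002  4.7161  0.0000
#> mean_width_m      0.2415 0.0624  3.8675  0.0001
#> cos_orientation   0.7916 1.3003  0.6088  0.5432
#> sin_orientation   2.0990 0.6462  3.2484  0.0013
#> sigma2 = 7.327, logLik = -576.660, AIC = 1169.32
#> F = 11.769 on 4 and 245 df, p = 9.259e-09
```

Reading this: the scan located the connectivity scale at 3.0 km — one
grid step from this world's planted R* = 2.9 km. The drivers fit
recovered the planted biomass coefficient (1.1e-3 → 0.0010) and width
coefficient (0.2 → 0.24); the wave term (planted weak) was dropped by
AIC. `phi` ≈ 0.67 recovers the planted alongshore AR coefficient 0.6;
`theta` differs from the planted monthly value because averaging months
re-parameterizes the MA component (see the vignette).

The same chain runs from the command line, with CSV/JSON artifacts and
a checksummed reproducibility manifest:

```sh
Rscript -e 'wrackscale::wrackscale_cli()' report \
  --design local --seed 7 --out runs/local7
```

## Layout

- `R/`, `src/` — implementation (GLS/ARMA core partly in C++ via Rcpp)
- `tests/testthat/` — unit, property, and acceptance tests
- `scripts/acceptance.R` — acceptance report entry point
- `vignettes/wrackscale-methods.Rmd` — methods and design rationale
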