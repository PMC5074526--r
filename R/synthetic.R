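# Virtual climates and virtual species with analytically known suitability,
# so every pipeline stage can be validated against ground truth without
# external downloads. The virtual climate is a latitudinal temperature
# gradient with a seasonal cycle and spatially smoothed noise; the future
# scenario is the baseline plus a uniform warming and a precipitation
# multiplier. The virtual species has a Gaussian niche on derived bioclim
# variables (standard virtual-species practice), so its true suitability
# and true suitable area are exact.

# white noise convolved with a normalized square kernel: cheap spatial
# autocorrelation without geostatistics machinery
smooth_noise <- function(n_rows, n_cols, sd = 1, kernel = 5L) {
  pad <- kernel %/% 2L
  z <- matrix(stats::rnorm((n_rows + 2L * pad) * (n_cols + 2L * pad)),
              n_rows + 2L * pad, n_cols + 2L * pad)
  k <- rep(1 / kernel, kernel)
  # separable convolution along rows then columns
  z <- apply(z, 2L, function(col) stats::filter(col, k, sides = 2L))
  z <- t(apply(z, 1L, function(row) stats::filter(row, k, sides = 2L)))
  core <- z[pad + seq_len(n_rows), pad + seq_len(n_cols)]
  core * sd / stats::sd(as.vector(core))
}

#' Generate a baseline and future virtual climate
#'
#' Monthly mean temperature follows
#' `a - b * |lat| + A * cos(2 * pi * (m - 7) / 12) + noise` (warmest in
#' July), with `tmin`/`tmax` a fixed half-range below/above it; monthly
#' precipitation follows an analogous latitudinal + seasonal form, floored
#' at zero. The noise is a seeded, spatially smoothed field shared across
#' months. The future climate is the baseline with `delta_t` degrees added
#' to every temperature and precipitation multiplied by `precip_factor` —
#' a known uniform shift, so e.g. future BIO1 minus baseline BIO1 equals
#' `delta_t` exactly at every cell.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed for the noise fields.
#' @param temp_intercept Sea-level-equator-style intercept `a`, default 25.
#' @param temp_lat_gradient Cooling per degree of |latitude| `b`, default
#'   0.5 (deg C per deg lat).
#' @param seasonal_amplitude Seasonal half-amplitude `A`, default 15 deg C.
#' @param diurnal_half_range Half of tmax - tmin, default 5 deg C.
#' @param temp_noise_sd SD of the smoothed temperature noise, default 0.5.
#' @param prec_intercept,prec_lat_gradient,prec_seasonal_amplitude Monthly
#'   precipitation parameters (mm), defaults 120, 1, 30.
#' @param prec_noise_sd SD of the smoothed precipitation noise, default 8.
#' @param delta_t Uniform warming applied to the future, default +3 deg C.
#' @param precip_factor Future precipitation multiplier, default 1.1.
#' @return List with `baseline` and `future` [monthly_climate()] objects
#'   and the parameters used.
#' @export
generate_climate <- function(spec, seed = 1L, temp_intercept = 25,
                             temp_lat_gradient = 0.5,
                             seasonal_amplitude = 15,
                             diurnal_half_range = 5, temp_noise_sd = 0.5,
                             prec_intercept = 120, prec_lat_gradient = 1,
                             prec_seasonal_amplitude = 30,
                             prec_noise_sd = 8, delta_t = 3,
                             precip_factor = 1.1) {
  stopifnot(inherits(spec, "grid_spec"))
  if (precip_factor <= 0) stop("precip_factor must be > 0")
  lat <- matrix(cell_centers(spec)$lat, spec$n_rows, spec$n_cols)
  noise <- with_seed(seed, list(
    t = smooth_noise(spec$n_rows, spec$n_cols, temp_noise_sd),
    p = smooth_noise(spec$n_rows, spec$n_cols, prec_noise_sd)))
  month_layers <- function(base_fun, prefix) {
    lapply(1:12, function(m)
      grid_layer(spec, base_fun(m), sprintf("%s_%02d", prefix, m)))
  }
  tmean <- function(m) temp_intercept - temp_lat_gradient * abs(lat) +
    seasonal_amplitude * cos(2 * pi * (m - 7) / 12) + noise$t
  prec <- function(m) pmax(
    prec_intercept - prec_lat_gradient * abs(lat) +
      prec_seasonal_amplitude * cos(2 * pi * (m - 1) / 12) + noise$p, 0)
  baseline <- monthly_climate(
    tmin = month_layers(function(m) tmean(m) - diurnal_half_range, "tmin"),
    tmax = month_layers(function(m) tmean(m) + diurnal_half_range, "tmax"),
    prec = month_layers(prec, "prec"))
  future <- monthly_climate(
    tmin = lapply(baseline$tmin, function(l)
      grid_layer(spec, l$values + delta_t, l$name)),
    tmax = lapply(baseline$tmax, function(l)
      grid_layer(spec, l$values + delta_t, l$name)),
    prec = lapply(baseline$prec, function(l)
      grid_layer(spec, l$values * precip_factor, l$name)))
  list(baseline = baseline, future = future,
       params = list(seed = seed, delta_t = delta_t,
                     precip_factor = precip_factor))
}

#' Define a virtual species with a Gaussian niche
#'
#' True suitability is `s(x) = exp(-sum_v (v(x) - mu_v)^2 / (2 sigma_v^2))`
#' over the named niche variables (default annual mean temperature BIO1 and
#' annual precipitation BIO12), so `s` is in `(0, 1]` and analytic. Cells
#' with `s >= cutoff` count as truly suitable.
#'
#' The default optimum (BIO1 = 6 deg C, BIO12 = 850 mm) sits just beyond
#' the warm edge of the default virtual climate's baseline (annual means
#' about -5 to 5 deg C on a 40-60 deg latitude grid), so a uniform warming
#' moves the thermal optimum poleward onto the grid and expands the truly
#' suitable area — the poleward-expansion situation the pipeline is meant
#' to rank. The default breadths define a strong niche: under the default
#' climate the suitability truth itself separates suitability-weighted
#' presences from uniform background cells with an AUC of about 0.9, so a
#' well-specified model fitted to ample data can discriminate excellently.
#'
#' @param mu Named optima per niche variable.
#' @param sigma Named niche breadths (> 0), same names as `mu`.
#' @param cutoff Suitability cutoff for "truly suitable", default 0.5.
#' @param name Species name used in generated occurrence sets.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(mu = c(BIO1 = 6, BIO12 = 850),
                            sigma = c(BIO1 = 1.5, BIO12 = 200),
                            cutoff = 0.5, name = "virtual species") {
  if (!identical(sort(names(mu)), sort(names(sigma))))
    stop("mu and sigma must have identical variable names")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (cutoff < 0) stop("cutoff must be >= 0")
  structure(list(variables = names(mu), mu = mu, sigma = sigma[names(mu)],
                 cutoff = cutoff, name = name),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' @param sp A [virtual_species()].
#' @param stack A [climate_stack()] containing the niche variables.
#' @return A `grid_layer` of true suitability in `(0, 1]`.
#' @export
true_suitability <- function(sp, stack) {
  stopifnot(inherits(sp, "virtual_species"), inherits(stack, "climate_stack"))
  missing <- setdiff(sp$variables, names(stack$layers))
  if (length(missing))
    stop("stack is missing niche variable(s): ",
         paste(missing, collapse = ", "))
  z <- 0
  for (v in sp$variables)
    z <- z + (stack$layers[[v]]$values - sp$mu[[v]])^2 / (2 * sp$sigma[[v]]^2)
  grid_layer(stack$spec, exp(-z), name = paste0("true_suitability"))
}

#' Sample presence points proportional to true suitability
#'
#' Draws `n` cells (with replacement) with probability proportional to the
#' species' true suitability over the stack's valid cells, and places each
#' record at the cell centre.
#'
#' @param sp A [virtual_species()], or `NULL` when `uniform = TRUE`.
#' @param stack A [climate_stack()] with the niche variables.
#' @param n Number of presence records.
#' @param seed Integer seed.
#' @param uniform If `TRUE`, ignore suitability and sample valid cells
#'   uniformly (the niche-free null used for calibration checks).
#' @return An [occurrence_set()].
#' @export
sample_presences <- function(sp, stack, n = 500L, seed = 1L,
                             uniform = FALSE) {
  cells <- valid_cells(stack)
  if (!length(cells)) stop("stack has no valid cells")
  w <- if (uniform) rep(1, length(cells))
       else true_suitability(sp, stack)$values[cells]
  if (!any(w > 0)) stop("true suitability is zero on every valid cell")
  picked <- with_seed(seed, sample(cells, n, replace = TRUE, prob = w))
  ctr <- cell_centers(stack$spec, picked)
  occurrence_set(if (is.null(sp)) "niche-free" else sp$name,
                 ctr$lon, ctr$lat,
                 provenance = sprintf("simulated (seed %d)", seed))
}

#' True suitable area of a virtual species
#'
#' Area (km^2) of valid cells whose true suitability is at least the
#' cutoff — exact ground truth for parameter-recovery checks.
#'
#' @param sp A [virtual_species()].
#' @param stack A [climate_stack()].
#' @param areas Cell-area layer from [cell_areas()]; computed from the
#'   stack's grid when omitted.
#' @param cutoff Suitability cutoff; defaults to the species' own.
#' @return Area in km^2.
#' @export
true_suitable_area <- function(sp, stack, areas = NULL, cutoff = NULL) {
  if (is.null(areas)) areas <- cell_areas(stack$spec)
  if (is.null(cutoff)) cutoff <- sp$cutoff
  s <- true_suitability(sp, stack)$values
  sum(areas$values[which(s >= cutoff)])
}

#' Simulate a complete single-species study
#'
#' Convenience wrapper tying the generator together: virtual climate
#' (baseline + future), derived bioclim stacks, a virtual species, sampled
#' presences on the baseline, and the true suitable areas in both periods.
#'
#' @param spec A [grid_spec()]; default the 100 x 100 cell, 0.2-degree grid
#'   spanning latitudes 40-60.
#' @param seed Master seed; the climate uses `seed`, presence sampling
#'   `seed + 1`.
#' @param n_presences Number of presence records, default 500.
#' @param species A [virtual_species()]; default niche on BIO1 and BIO12.
#' @param ... Passed to [generate_climate()].
#' @return List with `spec`, `species`, `climate`, `baseline_bioclim`,
#'   `future_bioclim`, `occurrences`, `areas`, `true_area_baseline`,
#'   `true_area_future`.
#' @export
simulate_study <- function(spec = grid_spec(100, 100, x_min = -120,
                                            y_min = 40, cell_size = 0.2),
                           seed = 1L, n_presences = 500L,
                           species = virtual_species(), ...) {
  clim <- generate_climate(spec, seed = seed, ...)
  baseline <- derive_bioclim(clim$baseline)
  future <- derive_bioclim(clim$future)
  occ <- sample_presences(species, baseline, n = n_presences,
                          seed = seed + 1L)
  areas <- cell_areas(spec)
  list(spec = spec, species = species, climate = clim,
       baseline_bioclim = baseline, future_bioclim = future,
       occurrences = occ, areas = areas,
       true_area_baseline = true_suitable_area(species, baseline, areas),
       true_area_future = true_suitable_area(species, future, areas))
}
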