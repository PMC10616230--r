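## Synthetic data with known ground truth: daily site weather with seasonal
## cycles (and an optional drying trend injected through relative humidity),
## and multi-tree ring-width series generated from the same log-linear
## growth model the estimation stage fits, so parameter recovery is testable
## end to end without any external data.

#' Per-site climate parameters for the weather simulator
#'
#' @param mat Mean annual temperature, degrees C.
#' @param map Mean annual precipitation, mm.
#' @param seasonal_amplitude Half-range of the seasonal temperature cycle,
#'   degrees C (>= 0).
#' @param diurnal_range Mean Tmax - Tmin, degrees C (>= 0).
#' @param temp_noise_sd SD of daily temperature anomalies, degrees C.
#' @param temp_noise_ar1 AR1 coefficient of daily temperature anomalies.
#' @param interannual_sd SD of year-level mean temperature anomalies,
#'   degrees C: gives summers realistic year-to-year spread beyond what
#'   daily noise averages down to.
#' @param interannual_ar1 AR1 coefficient of the year-level anomalies
#'   (temperature and humidity): observed summer climate has multi-year
#'   persistence, which any serial-inference correction downstream must
#'   face.
#' @param rh_interannual_sd SD of year-level relative humidity anomalies,
#'   percentage points.
#' @param rh_mean Mean relative humidity, percent.
#' @param rh_sd Daily SD of relative humidity, percent.
#' @param rh_trend Linear RH change, percentage points per year (negative
#'   values produce a rising-VPD trend while keeping VPD internally
#'   consistent with temperature). The default -0.09 pp/yr reproduces the
#'   observed boreal summer VPD rise of roughly +0.1 kPa over six decades;
#'   set 0 for a stationary climate.
#' @param p_wet_dry,p_wet_wet Precipitation occurrence chain: probability of
#'   a wet day after a dry (resp. wet) day.
#' @param gamma_shape Shape of the gamma distribution of wet-day amounts.
#' @param lat,lon,elev Site coordinates and elevation.
#' @return A `site_params` list.
#' @export
site_params <- function(mat = 1.5, map = 800, seasonal_amplitude = 16,
                        diurnal_range = 8, temp_noise_sd = 3,
                        temp_noise_ar1 = 0.7, interannual_sd = 0.8,
                        interannual_ar1 = 0.3,
                        rh_interannual_sd = 3, rh_mean = 70, rh_sd = 6,
                        rh_trend = -0.09, p_wet_dry = 0.25, p_wet_wet = 0.55,
                        gamma_shape = 0.8, lat = 52, lon = -93.5, elev = 350) {
  if (seasonal_amplitude < 0 || diurnal_range < 0)
    stop_config("amplitudes must be >= 0")
  if (rh_mean <= 0 || rh_mean > 100) stop_config("invalid RH regime")
  structure(as.list(environment()), class = "site_params")
}

#' Simulation configuration for the coupled weather/ring generator
#'
#' The generative model for each tree is the same log-linear growth model
#' the package fits: `log BAI(t) = alpha * log BA(t-1) + f(age) +
#' beta1 * VPD(t) + beta2 * VPD(t-1) + b_tree + e(t)` with `b_tree ~
#' N(0, sigma_tree^2)` and `e` an AR1 process with coefficient `phi` and
#' innovation SD `sigma_eps`. The age curve `f` is a two-parameter
#' log-normal-shaped stand-in for the fitted age smooth:
#' `f(age) = height * exp(-(log(age / peak))^2 / (2 width^2))`.
#'
#' @param n_sites Number of sites.
#' @param trees_per_site Trees per site (>= 1).
#' @param years Inclusive calendar year range of the weather record; must
#'   span >= 25 years so downstream model fitting can be attempted.
#' @param species_labels Species assigned to sites (recycled).
#' @param alpha Elasticity of prior basal area (default 0.3).
#' @param beta1,beta2 Current- and prior-summer VPD effects on log BAI, per
#'   kPa (defaults -0.4, -1.0).
#' @param age_curve List `height`, `peak`, `width` of the log-normal-shaped
#'   age curve (defaults 1.5, 30 yr, 0.8), or an arbitrary `function(age)`.
#' @param sigma_tree SD of the tree random intercept (default 0.15).
#' @param phi AR1 coefficient of residuals, in (-1, 1) (default 0.5).
#' @param sigma_eps AR1 innovation SD (default 0.25).
#' @param init_radius_meanlog,init_radius_sdlog Log-normal parameters of the
#'   initial (age-0) stem radius in cm (defaults log(0.1), 0.2): keeps
#'   BA(t-1) positive in the first modelled year.
#' @param germination_spread Trees germinate uniformly within this many
#'   years after the record start (default 20): mixed-age stands decouple
#'   tree age from calendar year, which is what identifies the age smooth
#'   against the year-varying climate covariates. 0 gives a single cohort.
#' @param climate_params A `site_params` or list of them (one per site).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 10, trees_per_site = 5, years = 1959:2018,
                       species_labels = c("PICEMAR", "PICEGLA", "PINUBAN"),
                       alpha = 0.3, beta1 = -0.4, beta2 = -1.0,
                       age_curve = list(height = 1.5, peak = 30, width = 0.8),
                       sigma_tree = 0.15, phi = 0.5, sigma_eps = 0.25,
                       init_radius_meanlog = log(0.1), init_radius_sdlog = 0.2,
                       germination_spread = 20,
                       climate_params = site_params(), seed = 1L) {
  if (abs(phi) >= 1) stop_config("phi must be in (-1, 1)")
  if (sigma_tree < 0 || sigma_eps < 0) stop_config("SDs must be >= 0")
  if (length(years) < 25) stop_config("years must span >= 25 for model fitting")
  if (trees_per_site < 1) stop_config("trees_per_site must be >= 1")
  structure(as.list(environment()), class = "sim_config")
}

age_curve_value <- function(age, curve) {
  if (is.function(curve)) return(curve(age))
  curve$height * exp(-(log(age / curve$peak))^2 / (2 * curve$width^2))
}

#' Simulate daily site weather
#'
#' Sinusoidal seasonal temperature cycle around the configured mean annual
#' temperature with AR1 daily anomalies, a two-state (wet/dry) occurrence
#' chain with gamma wet-day amounts scaled to the configured annual total,
#' and Gaussian relative humidity with an optional linear trend.
#'
#' @param params A [site_params()].
#' @param years Integer vector of calendar years.
#' @param seed RNG seed.
#' @return Data frame `date, tmin, tmax, prcp, rh`, one row per calendar day.
#' @export
simulate_daily_weather <- function(params, years, seed = 1L) {
  stopifnot(inherits(params, "site_params"))
  if (length(years) == 0) stop_config("years must be non-empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  # seasonal cycle peaking ~July 20 (doy 201) in the northern hemisphere
  seas <- params$seasonal_amplitude * cos(2 * pi * (doy - 201) / 365.25)
  anom <- numeric(n)
  if (params$temp_noise_sd > 0) {
    innov_sd <- params$temp_noise_sd * sqrt(1 - params$temp_noise_ar1^2)
    z <- stats::rnorm(n, 0, innov_sd)
    anom <- stats::filter(z, params$temp_noise_ar1, method = "recursive")
    anom <- as.numeric(anom)
  }
  yr_levels <- sort(unique(yr))
  ar1_series <- function(n, sd, rho) {
    if (sd <= 0) return(numeric(n))
    as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - rho^2)),
                             rho, method = "recursive"))
  }
  yr_anom <- ar1_series(length(yr_levels), params$interannual_sd,
                        params$interannual_ar1)
  tmean <- params$mat + seas + anom + yr_anom[match(yr, yr_levels)]
  half_dr <- params$diurnal_range / 2
  tmin <- tmean - half_dr
  tmax <- tmean + half_dr
  # precipitation: occurrence chain then gamma amounts
  prcp <- numeric(n)
  if (params$map > 0) {
    wet <- logical(n)
    pw <- params$p_wet_dry / (1 + params$p_wet_dry - params$p_wet_wet)
    wet[1] <- stats::runif(1) < pw
    u <- stats::runif(n)
    for (i in 2:n) {
      wet[i] <- u[i] < if (wet[i - 1]) params$p_wet_wet else params$p_wet_dry
    }
    exp_wet_frac <- pw
    mean_amount <- params$map / (365.25 * exp_wet_frac)
    amounts <- stats::rgamma(n, shape = params$gamma_shape,
                             scale = mean_amount / params$gamma_shape)
    prcp[wet] <- amounts[wet]
  }
  rh_yr <- ar1_series(length(yr_levels), params$rh_interannual_sd,
                      params$interannual_ar1)
  rh <- params$rh_mean + params$rh_trend * (yr - yr[1]) +
    rh_yr[match(yr, yr_levels)] + stats::rnorm(n, 0, params$rh_sd)
  rh <- pmin(pmax(rh, 2), 100)
  data.frame(date = dates, tmin = tmin, tmax = tmax, prcp = prcp, rh = rh)
}

## Save/restore .Random.seed so simulators do not disturb the caller's RNG.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate ring-width series for one site from the generative growth model
#'
#' Each tree draws a random intercept and an AR1 residual series, builds
#' log BAI recursively through the basal-area feedback `BA(t) = BA(t-1) +
#' BAI(t)`, and converts BAI back to ring widths by inverting the annulus
#' relation. Trees germinate in the first weather year, so ring ages run
#' from 1 in `years[2]` (the first year with a prior-summer VPD).
#'
#' @param config A [sim_config()].
#' @param site_climate Site-year climate with `year` and `vpd_summer`
#'   covering all simulated ring years plus the preceding year.
#' @param site_id Site identifier.
#' @param species Species label.
#' @param seed RNG seed.
#' @return List with `series` (list of [ring_series()]), and `truth`: the
#'   generating parameters, per-tree intercepts, initial radii, and the
#'   simulated per-tree log-BAI residual series.
#' @export
simulate_ring_series <- function(config, site_climate, site_id = "S001",
                                 species = NULL, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  species <- species %||% config$species_labels[1]
  ring_years <- (min(config$years) + 1):max(config$years)
  need_years <- c(min(ring_years) - 1, ring_years)
  if (!all(need_years %in% site_climate$year))
    stop_config("site_climate must cover years %d-%d", min(need_years),
                max(need_years))
  vpd <- site_climate$vpd_summer[match(need_years, site_climate$year)]
  if (any(is.na(vpd))) stop_config("missing summer VPD in site_climate")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  spread <- min(config$germination_spread,
                max(length(ring_years) - 25, 0))
  series <- vector("list", config$trees_per_site)
  intercepts <- numeric(config$trees_per_site)
  r0s <- numeric(config$trees_per_site)
  offsets <- integer(config$trees_per_site)
  resid_list <- vector("list", config$trees_per_site)
  for (k in seq_len(config$trees_per_site)) {
    # first tree spans the whole record; the rest germinate later
    off <- if (k == 1L || spread == 0) 0L else sample.int(spread + 1L, 1L) - 1L
    yrs_k <- ring_years[ring_years >= min(ring_years) + off]
    n_yr <- length(yrs_k)
    vpd_k <- vpd[match(yrs_k, need_years)]
    vpd_k_prev <- vpd[match(yrs_k - 1L, need_years)]
    b <- if (config$sigma_tree > 0) stats::rnorm(1, 0, config$sigma_tree) else 0
    r0 <- stats::rlnorm(1, config$init_radius_meanlog, config$init_radius_sdlog)
    e <- numeric(n_yr)
    if (config$sigma_eps > 0) {
      e[1] <- stats::rnorm(1, 0, config$sigma_eps / sqrt(1 - config$phi^2))
      innov <- stats::rnorm(n_yr, 0, config$sigma_eps)
      for (t in seq_len(n_yr)[-1]) e[t] <- config$phi * e[t - 1] + innov[t]
    }
    ba_prev <- pi * r0^2
    widths <- numeric(n_yr)
    r_prev <- r0
    for (t in seq_len(n_yr)) {
      lb <- config$alpha * log(ba_prev) +
        age_curve_value(t, config$age_curve) +
        config$beta1 * vpd_k[t] + config$beta2 * vpd_k_prev[t] + b + e[t]
      bai <- exp(lb)
      if (!is.finite(bai) || bai <= 0)
        stop_config("simulation produced BAI <= 0 for tree %d, year %d",
                    k, yrs_k[t])
      ba <- ba_prev + bai
      r <- sqrt(ba / pi)
      widths[t] <- (r - r_prev) * 10  # cm -> mm
      r_prev <- r
      ba_prev <- ba
    }
    tree_id <- sprintf("%s_T%02d", site_id, k)
    series[[k]] <- ring_series(tree_id, site_id, species, min(yrs_k), widths)
    intercepts[k] <- b
    r0s[k] <- r0
    offsets[k] <- off
    resid_list[[k]] <- e
  }
  truth <- list(site_id = site_id, species = species,
                alpha = config$alpha, beta1 = config$beta1,
                beta2 = config$beta2, phi = config$phi,
                sigma_tree = config$sigma_tree, sigma_eps = config$sigma_eps,
                age_curve = config$age_curve,
                intercepts = intercepts, init_radius = r0s,
                germination_offsets = offsets,
                years = ring_years, residuals = resid_list, seed = seed)
  list(series = series, truth = truth)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Writes ring widths (Tucson/rwl), daily weather CSVs, site metadata CSV,
#' and the ground-truth JSON, with consistent identifiers, so the bundle
#' round-trips through the package's own readers.
#'
#' @param ring_series_list List of [ring_series()].
#' @param weather_list Named list (by site_id) of daily weather data frames.
#' @param site_meta Data frame `site_id, species, lat, lon, elev`.
#' @param truth Ground-truth list (JSON-serialisable).
#' @param out_dir Output directory (created if needed).
#' @param precision rwl width quantum in mm (default 0.001).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture_bundle <- function(ring_series_list, weather_list, site_meta,
                                 truth, out_dir, precision = 0.001) {
  if (length(ring_series_list) == 0) stop_config("empty series set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rings = file.path(out_dir, "rings.rwl"),
             site_meta = file.path(out_dir, "sites.csv"),
             truth = file.path(out_dir, "truth.json"))
  write_rwl(ring_series_list, paths[["rings"]], precision = precision)
  utils::write.csv(site_meta, paths[["site_meta"]], row.names = FALSE)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  for (sid in names(weather_list)) {
    p <- file.path(out_dir, sprintf("weather_%s.csv", sid))
    utils::write.csv(weather_list[[sid]], p, row.names = FALSE)
    paths[[paste0("weather_", sid)]] <- p
  }
  invisible(paths)
}
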