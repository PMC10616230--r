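## Climate covariates: daily VPD, potential evapotranspiration, a daily soil
## moisture index from a quadratic-plus-linear water balance, and site-year
## summer (JJA) summaries with long-term climatologies.

#' Saturation vapour pressure (Tetens/FAO-56 form)
#'
#' Computes the saturation vapour pressure of air at a given temperature,
#' `es(T) = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa. This is the standard
#' form used for reference evapotranspiration and vapour pressure deficit
#' calculations.
#'
#' @param temp_c Air temperature in degrees Celsius (vectorised).
#' @return Saturation vapour pressure in kPa.
#' @examples
#' saturation_vapour_pressure(0)   # 0.6108
#' saturation_vapour_pressure(20)  # ~2.338
#' @export
saturation_vapour_pressure <- function(temp_c) {
  if (!is.numeric(temp_c) || any(!is.finite(temp_c)))
    stop_config("temperature must be finite numeric")
  if (any(temp_c <= -100)) stop_config("temperature below -100 C is not supported")
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Actual vapour pressure from relative humidity
#'
#' `ea = es(Tmean) * rh / 100`, with `es` evaluated at the daily mean
#' temperature.
#'
#' @param tmean_c Daily mean temperature, degrees C.
#' @param rh Relative humidity, percent in (0, 100].
#' @return Actual vapour pressure, kPa.
#' @export
actual_vapour_pressure <- function(tmean_c, rh) {
  if (any(!is.finite(rh)) || any(rh <= 0) || any(rh > 100))
    stop_config("relative humidity must be in (0, 100]")
  saturation_vapour_pressure(tmean_c) * rh / 100
}

#' Estimate daily dewpoint temperature from Tmin and aridity
#'
#' Dewpoint regression in the spirit of Kimball-type methods that predict
#' dewpoint from daily minimum temperature corrected for site aridity: in
#' humid climates the night minimum approaches the dewpoint, while in arid
#' climates the dewpoint falls below Tmin. The correction is
#' `Tdew = Tmin - k * EF` where `EF` is an evaporative-fraction proxy
#' (annual potential evapotranspiration over annual precipitation, capped)
#' and `k` (degrees C per unit EF) controls the aridity depression.
#'
#' @param tmin_series Daily minimum temperature, degrees C; no missing values.
#' @param annual_prcp Annual precipitation total, mm (> 0).
#' @param pet_proxy Annual potential-evapotranspiration proxy, mm (>= 0).
#' @param k Aridity depression coefficient, degrees C (default 3).
#' @param ef_cap Upper cap on the evaporative fraction (default 3).
#' @return Daily dewpoint series, degrees C.
#' @export
estimate_dewpoint <- function(tmin_series, annual_prcp, pet_proxy, k = 3, ef_cap = 3) {
  if (any(is.na(tmin_series)))
    stop_config("missing Tmin on days: %s",
                paste(which(is.na(tmin_series)), collapse = ", "))
  assert_number(annual_prcp, "annual_prcp")
  if (annual_prcp <= 0) stop_config("annual_prcp must be > 0")
  ef <- min(pet_proxy / annual_prcp, ef_cap)
  tmin_series - k * ef
}

#' Daily vapour pressure deficit
#'
#' VPD is the mean of the saturation vapour pressures at the daily extremes
#' minus the actual vapour pressure, floored at zero:
#' `VPD = (es(Tmax) + es(Tmin)) / 2 - ea`.
#'
#' @param tmax,tmin Daily temperature extremes, degrees C (`tmax >= tmin`).
#' @param ea Actual vapour pressure, kPa (>= 0).
#' @return VPD in kPa, always >= 0. Supersaturated inputs (ea above the mean
#'   saturation pressure) are clamped to 0 with a warning.
#' @export
daily_vpd <- function(tmax, tmin, ea) {
  if (any(tmax < tmin)) stop_config("tmax must be >= tmin")
  if (any(ea < 0)) stop_config("actual vapour pressure must be >= 0")
  es_mean <- (saturation_vapour_pressure(tmax) + saturation_vapour_pressure(tmin)) / 2
  vpd <- es_mean - ea
  if (any(vpd < 0)) {
    warning("supersaturated input: VPD floored at 0", call. = FALSE)
    vpd <- pmax(vpd, 0)
  }
  vpd
}

## Extraterrestrial radiation (MJ m-2 day-1) from latitude and day-of-year,
## standard FAO-56 astronomy.
extraterrestrial_radiation <- function(lat_deg, doy) {
  if (any(lat_deg < -90 | lat_deg > 90)) stop_config("latitude outside [-90, 90]")
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(1, pmax(-1, x)))  # clamp handles polar day/night
  gsc <- 0.0820
  (24 * 60 / pi) * gsc * dr * (ws * sin(phi) * sin(delta) +
                                 cos(phi) * cos(delta) * sin(ws))
}

#' Daily potential evapotranspiration (simplified Penman-Monteith)
#'
#' Reference-surface Penman-Monteith evapotranspiration with the usual
#' simplifications for temperature-and-precipitation-only inputs: solar
#' radiation estimated from the diurnal temperature range
#' (`Rs = krs * sqrt(Tmax - Tmin) * Ra`), fixed albedo 0.23, default wind
#' speed, zero soil heat flux. All simplification constants are arguments,
#' not hard-coded behaviour.
#'
#' @param tmax,tmin Daily temperature extremes, degrees C.
#' @param ea Actual vapour pressure, kPa.
#' @param lat_deg Site latitude, degrees.
#' @param doy Day of year (1-366).
#' @param elev_m Site elevation, m (default 0); sets atmospheric pressure.
#' @param wind_ms Wind speed at 2 m, m/s (default 2).
#' @param krs Hargreaves radiation coefficient (default 0.17 for interior
#'   climates).
#' @return Daily PET, mm (>= 0).
#' @export
potential_evapotranspiration <- function(tmax, tmin, ea, lat_deg, doy,
                                         elev_m = 0, wind_ms = 2, krs = 0.17) {
  if (any(tmax < tmin)) stop_config("tmax must be >= tmin")
  tmean <- (tmax + tmin) / 2
  ra <- extraterrestrial_radiation(lat_deg, doy)
  rs <- krs * sqrt(pmax(tmax - tmin, 0)) * ra
  rso <- (0.75 + 2e-5 * elev_m) * ra
  # net shortwave minus net longwave (FAO-56 forms)
  rns <- (1 - 0.23) * rs
  sigma <- 4.903e-9
  tk4 <- ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2
  rel <- ifelse(rso > 0, pmin(pmax(rs / rso, 0.3), 1), 0.3)
  rnl <- sigma * tk4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn <- rns - rnl
  p_kpa <- 101.3 * ((293 - 0.0065 * elev_m) / 293)^5.26
  gamma <- 0.000665 * p_kpa
  delta <- 4098 * saturation_vapour_pressure(tmean) / (tmean + 237.3)^2
  es_mean <- (saturation_vapour_pressure(tmax) + saturation_vapour_pressure(tmin)) / 2
  vpd <- pmax(es_mean - ea, 0)
  et0 <- (0.408 * delta * rn + gamma * (900 / (tmean + 273)) * wind_ms * vpd) /
    (delta + gamma * (1 + 0.34 * wind_ms))
  pmax(et0, 0)
}

#' Construct a soil moisture state
#'
#' @param water_content Current soil water, mm.
#' @param capacity_critical Critical available water, mm (default 300): below
#'   this, evapotranspiration is soil-limited.
#' @param capacity_max Maximum available water, mm (default 400).
#' @return A `soil_moisture_state` list.
#' @export
soil_moisture_state <- function(water_content = 400, capacity_critical = 300,
                                capacity_max = 400) {
  if (capacity_critical >= capacity_max)
    stop_config("capacity_critical must be < capacity_max")
  if (water_content < 0 || water_content > capacity_max)
    stop_config("water_content must be in [0, capacity_max]")
  structure(list(water_content = water_content,
                 capacity_critical = capacity_critical,
                 capacity_max = capacity_max),
            class = "soil_moisture_state")
}

#' One daily step of the quadratic-plus-linear soil water balance
#'
#' Actual evapotranspiration is `pet * g(W)` where the response `g` ramps
#' quadratically below the critical capacity, `g(W) = (W/c)(2 - W/c)` for
#' `W < c`, and is unrestricted (`g = 1`) above it. Water is then updated as
#' `W' = clamp(W + prcp - AET, 0, capacity_max)`; the excess above capacity
#' runs off.
#'
#' @param state A `soil_moisture_state`.
#' @param prcp Daily precipitation, mm (>= 0).
#' @param pet Daily potential evapotranspiration, mm (>= 0).
#' @return Updated `soil_moisture_state` with attributes `aet` and `runoff`.
#' @export
step_soil_moisture <- function(state, prcp, pet) {
  stopifnot(inherits(state, "soil_moisture_state"))
  if (prcp < 0 || pet < 0) stop_config("negative forcing (prcp or pet < 0)")
  w <- state$water_content
  cc <- state$capacity_critical
  g <- if (w < cc) (w / cc) * (2 - w / cc) else 1
  aet <- pet * g
  w_raw <- w + prcp - aet
  runoff <- max(w_raw - state$capacity_max, 0)
  w_new <- min(max(w_raw, 0), state$capacity_max)
  out <- soil_moisture_state(w_new, cc, state$capacity_max)
  attr(out, "aet") <- aet
  attr(out, "runoff") <- runoff
  out
}

#' Soil moisture index over a daily forcing series
#'
#' Iterates [step_soil_moisture()] over aligned precipitation and PET series,
#' starting from full capacity, and reports the soil moisture index
#' `SMI = 100 * W / capacity_max` (percent of water-holding capacity). A
#' spin-up prefix can be discarded to remove initial-condition sensitivity.
#'
#' @param prcp,pet Daily forcing, mm.
#' @param capacity_critical,capacity_max QL parameters, mm (300 / 400).
#' @param spinup_days Leading days excluded from the output (default 0).
#' @return Numeric SMI series (percent), length `length(prcp) - spinup_days`.
#' @export
run_soil_moisture <- function(prcp, pet, capacity_critical = 300,
                              capacity_max = 400, spinup_days = 0) {
  stopifnot(length(prcp) == length(pet))
  st <- soil_moisture_state(capacity_max, capacity_critical, capacity_max)
  n <- length(prcp)
  w <- numeric(n)
  cc <- capacity_critical
  wc <- st$water_content
  for (i in seq_len(n)) {
    if (prcp[i] < 0 || pet[i] < 0) stop_config("negative forcing at day %d", i)
    g <- if (wc < cc) (wc / cc) * (2 - wc / cc) else 1
    wc <- min(max(wc + prcp[i] - pet[i] * g, 0), capacity_max)
    w[i] <- wc
  }
  smi <- 100 * w / capacity_max
  if (spinup_days > 0) smi <- smi[-seq_len(min(spinup_days, n))]
  smi
}

#' Derive daily VPD, PET and SMI from a daily weather table
#'
#' @param weather Data frame with columns `date` (Date), `tmin`, `tmax`,
#'   `prcp`, and optionally `rh`. If `rh` is absent, dewpoint is estimated
#'   from Tmin and site aridity ([estimate_dewpoint()]).
#' @param site_meta One-row data frame (or list) with at least `lat` and
#'   optionally `elev`.
#' @param smi_critical,smi_capacity Water-balance parameters, mm.
#' @param spinup_years Years of soil spin-up discarded from SMI memory: the
#'   balance is run over the full series but the first year starts from full
#'   capacity (default 1 simply re-runs the first year twice).
#' @return `weather` with added columns `vpd`, `pet`, `smi`.
#' @export
derive_daily_climate <- function(weather, site_meta, smi_critical = 300,
                                 smi_capacity = 400, spinup_years = 1) {
  need <- c("date", "tmin", "tmax", "prcp")
  if (!all(need %in% names(weather)))
    stop_config("weather must have columns %s", paste(need, collapse = ", "))
  if (any(weather$tmax < weather$tmin)) stop_config("tmax < tmin in weather")
  if (any(weather$prcp < 0)) stop_config("negative precipitation")
  lat <- site_meta$lat
  elev <- site_meta$elev %||% 0
  doy <- as.integer(format(weather$date, "%j"))
  tmean <- (weather$tmin + weather$tmax) / 2
  if (!is.null(weather$rh)) {
    ea <- actual_vapour_pressure(tmean, weather$rh)
  } else {
    # aridity proxy from a first PET pass with near-saturated air
    ea0 <- saturation_vapour_pressure(weather$tmin)
    pet0 <- potential_evapotranspiration(weather$tmax, weather$tmin, ea0,
                                         lat, doy, elev)
    yrs <- as.integer(format(weather$date, "%Y"))
    ann_p <- mean(tapply(weather$prcp, yrs, sum))
    ann_pet <- mean(tapply(pet0, yrs, sum))
    tdew <- estimate_dewpoint(weather$tmin, ann_p, ann_pet)
    ea <- saturation_vapour_pressure(pmin(tdew, weather$tmax))
  }
  weather$vpd <- daily_vpd(weather$tmax, weather$tmin, ea)
  weather$pet <- potential_evapotranspiration(weather$tmax, weather$tmin, ea,
                                              lat, doy, elev)
  nspin <- if (spinup_years > 0) {
    first_year <- format(weather$date[1], "%Y")
    sum(format(weather$date, "%Y") == first_year)
  } else 0L
  prcp_run <- c(weather$prcp[seq_len(nspin)], weather$prcp)
  pet_run <- c(weather$pet[seq_len(nspin)], weather$pet)
  weather$smi <- run_soil_moisture(prcp_run, pet_run, smi_critical,
                                   smi_capacity, spinup_days = nspin)
  weather
}

#' Assign a site to the nearest integer-degree grid node
#'
#' Nodes sit at integer latitude/longitude; the nearest node by great-circle
#' distance wins, with ties broken toward the equator and then westward.
#'
#' @param lat,lon Site coordinates, degrees.
#' @return Named numeric vector `c(lat, lon)` of the assigned node.
#' @export
assign_grid_node <- function(lat, lon) {
  cand <- expand.grid(lat = c(floor(lat), ceiling(lat)),
                      lon = c(floor(lon), ceiling(lon)))
  cand <- unique(cand)
  d <- haversine_km(lat, lon, cand$lat, cand$lon)
  # tolerance so exact midpoints tie; then |lat| asc, then lon asc (westmost)
  ord <- order(round(d, 6), abs(cand$lat), cand$lon)
  c(lat = cand$lat[ord[1]], lon = cand$lon[ord[1]])
}

#' Summer (JJA) site-year climate summaries and climatologies
#'
#' Aggregates a daily climate table (from [derive_daily_climate()]) to
#' site-year records: June-August mean VPD and SMI, plus long-term
#' climatologies (mean annual temperature MAT, mean annual precipitation MAP,
#' and long-term mean summer SMI) over the requested climatology period.
#' Years missing more than 10 percent of JJA days are flagged missing
#' (`NA`), never imputed.
#'
#' @param daily Daily table with `date`, `tmin`, `tmax`, `prcp`, `vpd`, `smi`.
#' @param years Integer vector of years to report.
#' @param site_id Site identifier attached to the output.
#' @param lat,lon Optional coordinates; when given, the output carries the
#'   assigned 1-degree grid node.
#' @param summer_months Months defining summer (default 6:8).
#' @return Data frame: `site_id`, `year`, `vpd_summer`, `smi_summer`, `mat`,
#'   `map`, `mean_summer_smi` (climatologies repeated within site).
#' @export
summarize_site_climate <- function(daily, years, site_id = "site",
                                   lat = NULL, lon = NULL, summer_months = 6:8) {
  yr <- as.integer(format(daily$date, "%Y"))
  mo <- as.integer(format(daily$date, "%m"))
  jja <- mo %in% summer_months
  full_jja <- sum(sapply(summer_months, function(m)
    c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]))
  out <- data.frame(site_id = site_id, year = years,
                    vpd_summer = NA_real_, smi_summer = NA_real_)
  for (i in seq_along(years)) {
    sel <- jja & yr == years[i]
    if (sum(sel) < 0.9 * full_jja) next  # flagged missing
    out$vpd_summer[i] <- mean(daily$vpd[sel])
    out$smi_summer[i] <- mean(daily$smi[sel])
  }
  tmean <- (daily$tmin + daily$tmax) / 2
  in_period <- yr %in% years
  out$mat <- mean(tapply(tmean[in_period], yr[in_period], mean))
  out$map <- mean(tapply(daily$prcp[in_period], yr[in_period], sum))
  out$mean_summer_smi <- mean(out$smi_summer, na.rm = TRUE)
  if (!is.null(lat) && !is.null(lon)) {
    node <- assign_grid_node(lat, lon)
    out$grid_lat <- node[["lat"]]
    out$grid_lon <- node[["lon"]]
  }
  out
}
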