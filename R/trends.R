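## Species-level detrending, percent growth change with
## autocorrelation-corrected confidence intervals, effective-sample-size
## trend tests, block-bootstrap correlation inference, and inverse-distance
## interpolation of site t-values onto a 1-degree grid.

#' Fit the species-level detrending model
#'
#' The growth model with the VPD covariates omitted: log BAI on log prior
#' basal area and the age smooth, with tree random intercepts and AR1
#' residuals. Its predictions capture growth variation attributable to tree
#' development stage; deviations from them are climate-related.
#'
#' @param data Model frame for one species pooled across sites (needs
#'   `tree_id, year, log_bai, log_ba_prev, age`).
#' @param spec A [growth_model_spec()]; `include_vpd` is forced off.
#' @return A `growth_model_fit`.
#' @export
fit_species_detrend <- function(data, spec = growth_model_spec()) {
  spec$include_vpd <- FALSE
  fit_growth_gamm(data, climate = NULL, spec = spec)
}

#' Percent growth change relative to the detrended prediction
#'
#' `GC = 100 * (BAI_obs - BAI_pred) / BAI_pred` per tree-year, on the
#' natural BAI scale. Predictions are back-transformed from the log scale
#' with a half-variance correction (`exp(pred + sigma^2/2)`, sigma^2 the
#' marginal residual variance) so the null expectation of GC is zero.
#' Tree-level deviations are averaged by year; the 95 percent confidence
#' interval uses a Student-t quantile on `n' - 1` degrees of freedom, where
#' the effective sample size `n'` shrinks the per-year tree count by the
#' lag-1 Moran's I of the mean GC series.
#'
#' @param detrend_fit A converged `growth_model_fit` from
#'   [fit_species_detrend()].
#' @param level Averaging unit for the species-year mean: `"tree"`
#'   (default) averages tree-level deviations directly; `"site"` first
#'   averages within site-year, then across sites.
#' @return Data frame `species, year, gc_mean, n_trees, n_effective,
#'   ci_low, ci_high` (percent), plus per-observation GC as attribute
#'   `gc_obs`.
#' @export
growth_change <- function(detrend_fit, level = c("tree", "site")) {
  stopifnot(inherits(detrend_fit, "growth_model_fit"))
  level <- match.arg(level)
  if (!isTRUE(detrend_fit$converged)) stop_config("detrend fit did not converge")
  d <- detrend_fit$data
  sig2_marg <- detrend_fit$sigma_eps_hat^2 / (1 - detrend_fit$phi_hat^2)
  pred <- exp(detrend_fit$fitted + sig2_marg / 2)
  if (any(pred <= 0)) stop_config("non-positive BAI prediction")
  gc <- 100 * (exp(d$log_bai) - pred) / pred
  if (level == "site") {
    # collapse to site-year means; downstream aggregation then weights
    # sites, not trees
    key <- paste(d$site_id, d$year)
    gc <- as.numeric(tapply(gc, key, mean)[key])[!duplicated(key)]
    d <- d[!duplicated(key), , drop = FALSE]
  }
  years <- sort(unique(d$year))
  gc_mean <- tapply(gc, d$year, mean)[as.character(years)]
  gc_sd <- tapply(gc, d$year, stats::sd)[as.character(years)]
  n_trees <- tapply(gc, d$year, length)[as.character(years)]
  I <- morans_i_lag1(as.numeric(gc_mean))
  out <- data.frame(species = d$species[1], year = years,
                    gc_mean = as.numeric(gc_mean),
                    n_trees = as.integer(n_trees))
  out$n_effective <- vapply(out$n_trees, function(n) effective_n(n, I),
                            numeric(1))
  half <- stats::qt(0.975, df = pmax(out$n_effective - 1, 1)) *
    as.numeric(gc_sd) / sqrt(out$n_effective)
  half[is.na(half)] <- 0
  out$ci_low <- out$gc_mean - half
  out$ci_high <- out$gc_mean + half
  attr(out, "gc_obs") <- data.frame(tree_id = d$tree_id, year = d$year,
                                    gc = gc)
  attr(out, "morans_i") <- I
  out
}

#' Lag-1 temporal Moran's I of a series
#'
#' Moran's I with binary lag-1 neighbour weights, which for a regular time
#' series is the lag-1 autocorrelation up to the `n/(n-1)` normalisation.
#'
#' @param series Numeric series (length >= 5).
#' @return Moran's I. A constant series returns `NA` with a warning.
#' @export
morans_i_lag1 <- function(series) {
  series <- series[!is.na(series)]
  n <- length(series)
  if (n < 5) stop_config("series too short for Moran's I (need >= 5)")
  z <- series - mean(series)
  denom <- sum(z^2)
  if (denom == 0) {
    warning("constant series: Moran's I undefined", call. = FALSE)
    return(NA_real_)
  }
  # sum over the symmetric lag-1 weight pairs / S0, times n
  (n / (2 * (n - 1))) * (2 * sum(z[-1] * z[-n])) / denom
}

#' Effective sample size under lag-1 autocorrelation
#'
#' `n' = n (1 - I) / (1 + I)`, clamped to `[2, n]`: positive persistence
#' shrinks the information content of n correlated observations; negative
#' or undefined I never inflates it.
#'
#' @param n Nominal sample size.
#' @param I Lag-1 Moran's I (or autocorrelation).
#' @return Effective sample size in `[2, n]` (returns `n` when I is NA).
#' @export
effective_n <- function(n, I) {
  if (is.na(I)) return(as.numeric(n))
  min(max(n * (1 - I) / (1 + I), 2), n)
}

#' Correlation with a stationary-block-bootstrap confidence interval
#'
#' Pearson correlation of two aligned annual series, with a 95 percent
#' percentile interval from a stationary block bootstrap applied to the
#' (x, y) pairs jointly. Resampling pairs in blocks preserves both the
#' serial autocorrelation (up to the expected block length, set from the
#' AR1 decorrelation time of the series) and the common trend contribution
#' within blocks. The OLS slope of y on x is also returned.
#'
#' @param x,y Aligned numeric series (length >= 15).
#' @param n_boot Bootstrap replicates (default 1000; < 200 warns).
#' @param seed RNG seed.
#' @param block_length Expected block length; default
#'   `max(2, (1 + rho) / (1 - rho))` with `rho` the larger lag-1
#'   autocorrelation of the two series (floored at 0).
#' @return List `r`, `ci_low`, `ci_high`, `ols_slope`, `block_length`,
#'   `n_boot`.
#' @export
boot_correlation <- function(x, y, n_boot = 1000, seed = 1L,
                             block_length = NULL) {
  n <- length(x)
  if (length(y) != n) stop_config("x and y must be aligned")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 15) stop_config("need >= 15 aligned years")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_config("degenerate variance in input series")
  if (n_boot < 200) warning("n_boot < 200: unstable CI", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- stats::cov(x, y) / stats::var(x)
  if (is.null(block_length)) {
    rho <- max(acf_lag1(x), acf_lag1(y), 0, na.rm = TRUE)
    rho <- min(rho, 0.95)
    block_length <- max(2, (1 + rho) / (1 - rho))
  }
  p_geo <- 1 / block_length
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    # stationary bootstrap: geometric block lengths, wrap-around continuation
    lens <- stats::rgeom(n, p_geo) + 1L
    starts <- sample.int(n, n, replace = TRUE)
    keep <- cumsum(lens) < n + max(lens)
    seqs <- sequence(lens[keep], from = starts[keep])
    idx <- ((seqs - 1L) %% n) + 1L
    idx <- idx[seq_len(n)]
    xb <- x[idx]; yb <- y[idx]
    rs[b] <- if (stats::sd(xb) > 0 && stats::sd(yb) > 0) stats::cor(xb, yb)
    else NA_real_
  }
  ci <- stats::quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(r = r, ci_low = min(ci[1], r), ci_high = max(ci[2], r),
       ols_slope = slope, block_length = block_length, n_boot = n_boot)
}

#' Linear trend test with an effective-sample-size correction
#'
#' OLS slope of the series on year; the slope's standard error is inflated
#' by `sqrt(n / n_eff)` where `n_eff = n (1 - r1) / (1 + r1)` uses the
#' lag-1 autocorrelation of the OLS residuals, and the two-sided t-test
#' runs on `n_eff - 2` degrees of freedom. This keeps the test's size near
#' nominal on serially persistent series, where naive OLS is strongly
#' anticonservative.
#'
#' @param values Numeric series (>= 10 points).
#' @param years Time axis (default `seq_along(values)`).
#' @param correct Apply the effective-sample-size correction (default TRUE;
#'   FALSE gives the naive OLS test).
#' @return List `slope` (units/yr), `se`, `t`, `p_adjusted`, `n`, `n_eff`,
#'   `intercept`. `p_adjusted` is `NA` (indeterminate) when `n_eff < 3`.
#' @export
trend_test <- function(values, years = seq_along(values), correct = TRUE) {
  ok <- !is.na(values)
  values <- values[ok]; years <- years[ok]
  n <- length(values)
  if (n < 10) stop_config("need >= 10 years for a trend test")
  xc <- years - mean(years)
  slope <- sum(xc * values) / sum(xc^2)
  intercept <- mean(values) - slope * mean(years)
  resid <- values - intercept - slope * years
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sum(xc^2))
  r1 <- acf_lag1(resid)
  n_eff <- if (correct && !is.na(r1)) effective_n(n, r1) else n
  se_adj <- se * sqrt(n / n_eff)
  tval <- slope / se_adj
  p <- if (n_eff < 3) NA_real_ else 2 * stats::pt(-abs(tval), df = n_eff - 2)
  list(slope = slope, se = se_adj, t = tval, p_adjusted = p, n = n,
       n_eff = n_eff, intercept = intercept)
}

#' Inverse-distance-weighted interpolation onto an integer-degree grid
#'
#' Each grid node takes the weighted mean of its `k` nearest sample values
#' (great-circle distance, weights `1/d^power`); a node coinciding with a
#' sample returns that sample's value exactly. The result is a convex
#' combination, so it never overshoots the neighbours' range.
#'
#' @param points Data frame with `lat`, `lon`.
#' @param values Sample values aligned with `points`.
#' @param grid_resolution Grid spacing in degrees (default 1).
#' @param k Number of neighbours (default 12; fewer points than k uses all,
#'   with a warning).
#' @param power IDW exponent (default 2).
#' @return Data frame `lon, lat, value` over the bounding box of the points.
#' @export
idw_interpolate <- function(points, values, grid_resolution = 1, k = 12,
                            power = 2) {
  n <- nrow(points)
  if (n < 1) stop_config("no sample points")
  if (n < k) {
    warning(sprintf("only %d points (< k = %d): using all", n, k),
            call. = FALSE)
    k <- n
  }
  lats <- seq(floor(min(points$lat)), ceiling(max(points$lat)),
              by = grid_resolution)
  lons <- seq(floor(min(points$lon)), ceiling(max(points$lon)),
              by = grid_resolution)
  grid <- expand.grid(lon = lons, lat = lats)
  grid$value <- NA_real_
  for (i in seq_len(nrow(grid))) {
    d <- haversine_km(grid$lat[i], grid$lon[i], points$lat, points$lon)
    o <- order(d)[seq_len(k)]
    if (d[o[1]] < 1e-9) {
      grid$value[i] <- values[o[1]]
    } else {
      w <- 1 / d[o]^power
      grid$value[i] <- sum(w * values[o]) / sum(w)
    }
  }
  grid
}
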