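# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## One standard 60-year site climate (weather -> daily VPD/SMI -> JJA
## summaries) used across model tests.
std_site_climate <- function() {
  if (is.null(.fixtures$sc)) {
    p <- site_params(mat = 2)
    wx <- simulate_daily_weather(p, 1959:2018, seed = 42)
    daily <- derive_daily_climate(wx, list(lat = 52, elev = 300))
    .fixtures$sc <- summarize_site_climate(daily, 1959:2018, "S001",
                                           lat = 52, lon = -93.5)
  }
  .fixtures$sc
}

## Model frame simulated from the generative model on the standard climate.
sim_model_frame <- function(seed = 7, ...) {
  sc <- std_site_climate()
  cfg <- sim_config(n_sites = 1, ...)
  rs <- simulate_ring_series(cfg, sc, site_id = "S001", seed = seed)
  bai <- lapply(lapply(rs$series, widths_to_bai), apply_juvenile_filter)
  list(mf = prepare_model_frame(bai, sc), truth = rs$truth, sc = sc)
}

## A cached converged detrending fit for growth-change tests.
std_detrend_fit <- function() {
  if (is.null(.fixtures$dt)) {
    sm <- sim_model_frame(seed = 11, trees_per_site = 6, beta1 = 0, beta2 = 0)
    .fixtures$dt <- fit_species_detrend(sm$mf)
    stopifnot(isTRUE(.fixtures$dt$converged))
  }
  .fixtures$dt
}

## Sensitivity-style table with a configurable signal variable.
make_sens_table <- function(n = 120, seed = 1, signal = "mat",
                            noise_sd = 0.5) {
  set.seed(seed)
  tab <- data.frame(
    elevation = runif(n, 200, 600), mat = runif(n, -2, 5),
    map = runif(n, 500, 1100), summer_smi = runif(n, 55, 95),
    species = sample(c("PICEMAR", "PICEGLA", "PINUBAN"), n, replace = TRUE),
    mean_age = runif(n, 40, 150), mean_ba = runif(n, 100, 900))
  sig <- if (is.null(signal)) rnorm(n) else if (signal == "species") {
    c(PICEMAR = -1, PICEGLA = 0, PINUBAN = 1)[tab$species]
  } else as.numeric(scale(tab[[signal]]))
  tab$t_value <- -1 - 1.5 * unname(sig) + rnorm(n, 0, noise_sd)
  tab
}

## Out-of-bag ensemble predictions for an rf_model.
oob_predictions <- function(forest) {
  n <- nrow(forest$X)
  acc <- numeric(n); cnt <- integer(n)
  for (b in seq_len(forest$n_trees)) {
    ob <- forest$oob[[b]]
    if (!length(ob)) next
    acc[ob] <- acc[ob] + vpdgrowth:::predict_tree(forest$trees[[b]],
                                                  forest$X[ob, , drop = FALSE])
    cnt[ob] <- cnt[ob] + 1L
  }
  ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
}

## Minimal stand-in growth_model_fit for classification/assembly unit tests.
fake_fit <- function(site_id, species = "PICEMAR", t1 = 0, p1 = 1,
                     t2 = 0, p2 = 1, converged = TRUE) {
  structure(list(
    converged = converged, reason = if (converged) NA_character_ else "fake",
    t = c(beta1 = t1, beta2 = t2), p = c(beta1 = p1, beta2 = p2),
    coef = c(beta1 = t1 / 10, beta2 = t2 / 10),
    site_id = site_id, species = species,
    spec = growth_model_spec(),
    data = data.frame(site_id = site_id, species = species)),
    class = "growth_model_fit")
}

## Gaussian AR1 series with stationary sd.
ar1_noise <- function(n, rho, sd = 1) {
  as.numeric(stats::filter(rnorm(n, 0, sd * sqrt(1 - rho^2)), rho,
                           method = "recursive"))
}
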