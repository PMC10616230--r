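test_that("degenerate constant climate produces a constant weather record", {
  p <- site_params(mat = 10, map = 0, seasonal_amplitude = 0,
                   diurnal_range = 0, temp_noise_sd = 0, interannual_sd = 0,
                   rh_sd = 0, rh_interannual_sd = 0, rh_trend = 0)
  wx <- simulate_daily_weather(p, 2000:2001, seed = 1)
  expect_true(all(wx$tmin == 10))
  expect_true(all(wx$tmax == 10))
  expect_true(all(wx$prcp == 0))
  expect_equal(nrow(wx), 731)  # one row per calendar day incl. leap day
})

test_that("long-run mean temperature honours the configured MAT", {
  p <- site_params(mat = 0, rh_trend = 0)
  wx <- simulate_daily_weather(p, 1989:2018, seed = 1)
  expect_lt(abs(mean((wx$tmin + wx$tmax) / 2)), 0.3)
  expect_true(all(wx$tmax >= wx$tmin))
  expect_true(all(wx$prcp >= 0))
  expect_true(all(wx$rh > 0 & wx$rh <= 100))
})

test_that("the configured drying trend appears in summer VPD", {
  p <- site_params(mat = 2, rh_trend = -0.15)
  wx <- simulate_daily_weather(p, 1959:2018, seed = 8)
  daily <- derive_daily_climate(wx, list(lat = 52))
  sc <- summarize_site_climate(daily, 1959:2018, "S")
  tr <- trend_test(sc$vpd_summer, sc$year, correct = FALSE)
  expect_gt(tr$slope, 0)
  expect_lt(tr$p_adjusted, 0.05)
})

test_that("weather generation is reproducible and seed-sensitive", {
  p <- site_params()
  w1 <- simulate_daily_weather(p, 2000:2005, seed = 33)
  w2 <- simulate_daily_weather(p, 2000:2005, seed = 33)
  w3 <- simulate_daily_weather(p, 2000:2005, seed = 34)
  expect_identical(w1, w2)
  expect_identical(dim(w1), dim(w3))
  expect_false(isTRUE(all.equal(w1$tmin, w3$tmin)))
  expect_error(site_params(rh_mean = 120), "RH")
  expect_error(site_params(seasonal_amplitude = -1), ">= 0")
})

test_that("noise-free equal-start trees are identical and follow the age curve", {
  sc <- std_site_climate()
  cfg <- sim_config(n_sites = 1, trees_per_site = 3, sigma_tree = 0,
                    sigma_eps = 0, beta1 = 0, beta2 = 0,
                    germination_spread = 0, init_radius_sdlog = 0, seed = 2)
  rs <- simulate_ring_series(cfg, sc, seed = 2)
  expect_equal(rs$series[[1]]$widths, rs$series[[2]]$widths)
  expect_equal(rs$series[[2]]$widths, rs$series[[3]]$widths)
  # BAI follows alpha * log BA(t-1) + f(age) exactly (invert Eq. 1 with the
  # true pith radius)
  b <- widths_to_bai(rs$series[[1]], pith_offset_cm = rs$truth$init_radius[1])
  f_age <- cfg$age_curve$height *
    exp(-(log(b$age / cfg$age_curve$peak))^2 / (2 * cfg$age_curve$width^2))
  expect_equal(log(b$bai), cfg$alpha * log(b$ba_prev) + f_age,
               tolerance = 1e-9)
})

test_that("a prior-summer VPD shift multiplies BAI by exp(beta2 * shift)", {
  sc <- std_site_climate()
  sc_hi <- sc
  sc_hi$vpd_summer <- sc$vpd_summer + 0.1
  cfg <- sim_config(n_sites = 1, trees_per_site = 2, alpha = 0, beta1 = 0,
                    beta2 = -1, sigma_tree = 0, sigma_eps = 0,
                    germination_spread = 0, init_radius_sdlog = 0, seed = 3)
  a <- simulate_ring_series(cfg, sc, seed = 3)
  b <- simulate_ring_series(cfg, sc_hi, seed = 3)
  bai_a <- widths_to_bai(a$series[[1]], a$truth$init_radius[1])$bai
  bai_b <- widths_to_bai(b$series[[1]], b$truth$init_radius[1])$bai
  expect_equal(bai_b / bai_a, rep(exp(-0.1), length(bai_a)),
               tolerance = 1e-10)
})

test_that("simulated residuals carry the configured AR1 coefficient", {
  sc <- std_site_climate()
  cfg <- sim_config(n_sites = 1, trees_per_site = 100, phi = 0.5,
                    germination_spread = 0, seed = 5)
  rs <- simulate_ring_series(cfg, sc, seed = 5)
  acfs <- vapply(rs$truth$residuals, acf_lag1, numeric(1))
  # sample lag-1 ACF carries the O(1/n) Marriott-Pope bias -(1+3*phi)/n;
  # compare the bias-corrected mean against the configured phi
  n <- length(rs$truth$residuals[[1]])
  acfs_c <- acfs + (1 + 3 * acfs) / n
  expect_lt(abs(mean(acfs_c) - 0.5), 0.03)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(phi = 1.2), "phi")
  expect_error(sim_config(sigma_eps = -1), ">= 0")
  expect_error(sim_config(years = 2000:2020), "25")
  expect_error(sim_config(trees_per_site = 0), ">= 1")
  sc <- std_site_climate()
  expect_error(simulate_ring_series(sim_config(years = 1950:2018), sc),
               "cover")
})

test_that("fixture bundles round-trip and keep counts consistent", {
  sc <- std_site_climate()
  out_dir <- withr::local_tempdir()
  series <- list(); weather <- list(); meta <- list(); truths <- list()
  for (s in 1:2) {
    sid <- sprintf("S%03d", s)
    cfg <- sim_config(n_sites = 1, trees_per_site = 3, seed = s)
    rs <- simulate_ring_series(cfg, sc, site_id = sid, seed = s)
    series <- c(series, rs$series)
    truths[[sid]] <- rs$truth
    weather[[sid]] <- simulate_daily_weather(site_params(), 2000:2002,
                                             seed = s)
    meta[[sid]] <- data.frame(site_id = sid, species = "PICEMAR", lat = 52,
                              lon = -93 - s, elev = 300)
  }
  paths <- write_fixture_bundle(series, weather, do.call(rbind, meta),
                                truths, out_dir)
  expect_true(all(file.exists(paths)))
  expect_length(list.files(out_dir, pattern = "^weather_"), 2)
  back <- read_rwl(file.path(out_dir, "rings.rwl"))
  expect_length(back, 6)
  ord <- match(vapply(series, `[[`, "", "tree_id"),
               vapply(back, `[[`, "", "tree_id"))
  for (i in seq_along(series)) {
    expect_equal(back[[ord[i]]]$widths, series[[i]]$widths,
                 tolerance = 0.001 / 1.9)
    expect_equal(back[[ord[i]]]$first_year, series[[i]]$first_year)
  }
  truth_back <- jsonlite::read_json(file.path(out_dir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(truth_back$S001$beta2, -1)
  expect_error(write_fixture_bundle(list(), weather, do.call(rbind, meta),
                                    truths, out_dir), "empty")
})
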