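test_that("effective sample size follows n(1-I)/(1+I) with clamps", {
  expect_equal(effective_n(100, 1 / 3), 50)
  expect_equal(effective_n(100, 0), 100)
  expect_equal(effective_n(100, -0.4), 100)  # never inflated
  expect_equal(effective_n(100, NA), 100)
  expect_equal(effective_n(10, 0.99), 2)     # floor
})

test_that("lag-1 Moran's I behaves like the lag-1 autocorrelation", {
  set.seed(14)
  ii <- replicate(60, morans_i_lag1(rnorm(100)))
  expect_lt(abs(mean(ii)), 0.05)
  pers <- replicate(30, morans_i_lag1(ar1_noise(200, 0.6)))
  expect_gt(mean(pers), 0.4)
  expect_warning(i0 <- morans_i_lag1(rep(3, 20)), "constant")
  expect_true(is.na(i0))
  expect_error(morans_i_lag1(1:3), ">= 5")
})

test_that("trend test recovers exact trends and ignores level shifts", {
  yrs <- 1951:2018
  tr <- trend_test(2 * yrs + 3, yrs)
  expect_equal(tr$slope, 2)
  expect_lt(tr$p_adjusted, 1e-10)
  set.seed(5)
  v <- 0.01 * yrs + rnorm(68, 0, 0.2)
  t1 <- trend_test(v, yrs)
  t2 <- trend_test(v + 100, yrs)
  expect_equal(t1$slope, t2$slope)
  expect_equal(t1$p_adjusted, t2$p_adjusted)
  expect_true(t1$n_eff <= t1$n)
  expect_error(trend_test(rnorm(5)), ">= 10")
})

test_that("bootstrap correlation handles exact, noisy and degenerate pairs", {
  x <- as.numeric(1:30)
  bc <- boot_correlation(x, x, n_boot = 250, seed = 1)
  expect_equal(bc$r, 1)
  expect_equal(bc$ci_low, 1)
  expect_equal(bc$ci_high, 1)
  set.seed(6)
  xx <- rnorm(60)
  yy <- 2 * xx + rnorm(60, 0, 0.4)
  bc2 <- boot_correlation(xx, yy, n_boot = 400, seed = 2)
  expect_equal(bc2$ols_slope, 2, tolerance = 0.15)
  expect_true(bc2$ci_low <= bc2$r && bc2$r <= bc2$ci_high)
  expect_error(boot_correlation(rep(1, 30), rnorm(30)), "degenerate")
  expect_error(boot_correlation(rnorm(10), rnorm(10)), ">= 15")
  expect_warning(boot_correlation(xx, yy, n_boot = 50, seed = 3), "n_boot")
})

test_that("block bootstrap widens intervals on persistent series", {
  set.seed(7)
  x <- ar1_noise(68, 0.7)
  y <- ar1_noise(68, 0.7)
  blk <- boot_correlation(x, y, n_boot = 500, seed = 4)
  iid <- boot_correlation(x, y, n_boot = 500, seed = 4,
                          block_length = 1 + 1e-9)
  expect_gt(blk$block_length, 2)
  expect_gt(blk$ci_high - blk$ci_low, iid$ci_high - iid$ci_low)
})

test_that("growth change is zero at the prediction and exact under scaling", {
  dt <- std_detrend_fit()
  sig2m <- dt$sigma_eps_hat^2 / (1 - dt$phi_hat^2)
  ident <- dt
  ident$data <- dt$data[order(dt$data$tree_id, dt$data$year), ]
  ident$data$log_bai <- dt$fitted + sig2m / 2
  gc0 <- suppressWarnings(growth_change(ident))  # constant series: Moran NA
  expect_lt(max(abs(gc0$gc_mean)), 1e-9)
  scaled <- ident
  scaled$data$log_bai <- ident$data$log_bai + log(1.1)
  gc10 <- growth_change(scaled)
  expect_equal(gc10$gc_mean, rep(10, nrow(gc10)), tolerance = 1e-9)
  # CI fields are coherent
  gc <- growth_change(dt)
  expect_true(all(gc$ci_low <= gc$gc_mean & gc$gc_mean <= gc$ci_high))
  expect_true(all(gc$n_effective <= gc$n_trees | gc$n_trees == 1))
  expect_error(growth_change(fake_fit("S", converged = FALSE)), "converge")
  # with a single site, site-level averaging reduces to the tree-level mean
  gc_site <- growth_change(dt, level = "site")
  expect_equal(gc_site$gc_mean, gc$gc_mean)
  expect_true(all(gc_site$n_trees == 1))
})

test_that("species detrend is the growth model with VPD terms removed", {
  sm <- sim_model_frame(seed = 81, trees_per_site = 4)
  d1 <- fit_species_detrend(sm$mf)
  d2 <- fit_growth_gamm(sm$mf, spec = growth_model_spec(include_vpd = FALSE))
  expect_true(d1$converged)
  expect_equal(d1$coef, d2$coef)
  expect_setequal(names(d1$coef), c("(Intercept)", "alpha"))
})

test_that("IDW interpolation is an exact, convex, nearest-neighbour blend", {
  set.seed(8)
  pts <- data.frame(lat = runif(30, 48, 56), lon = runif(30, -100, -80))
  vals <- rnorm(30)
  # force one sample onto a node
  pts$lat[1] <- 50; pts$lon[1] <- -90
  fld <- idw_interpolate(pts, vals, k = 12)
  at_node <- fld$value[fld$lat == 50 & fld$lon == -90]
  expect_equal(at_node, vals[1])
  expect_true(all(fld$value >= min(vals) - 1e-12 &
                    fld$value <= max(vals) + 1e-12))
  cst <- idw_interpolate(pts, rep(2.5, 30), k = 12)
  expect_equal(cst$value, rep(2.5, nrow(cst)))
  expect_warning(idw_interpolate(pts[1:5, ], vals[1:5], k = 12), "using all")
})
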