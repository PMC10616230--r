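test_that("noise-free simulation is recovered to high precision", {
  # degenerate world: no tree effect, iid 1e-8 noise, linear age effect (in
  # the spline span and penalty-free), true pith radius supplied so the
  # basal-area bookkeeping matches the generator exactly
  sc <- std_site_climate()
  cfg <- sim_config(n_sites = 1, trees_per_site = 5, sigma_tree = 0, phi = 0,
                    sigma_eps = 1e-8, age_curve = function(a) 1 + 0.01 * a,
                    seed = 7)
  rs <- simulate_ring_series(cfg, sc, site_id = "S001", seed = 7)
  bai <- Map(function(s, r0) apply_juvenile_filter(widths_to_bai(s, r0)),
             rs$series, rs$truth$init_radius)
  fit <- fit_growth_gamm(prepare_model_frame(bai, sc),
                         spec = growth_model_spec(fixed_phi = 0,
                                                  fixed_tau = 0))
  expect_true(fit$converged)
  expect_equal(unname(fit$coef["alpha"]), cfg$alpha, tolerance = 1e-3)
  expect_equal(unname(fit$coef["beta1"]), cfg$beta1, tolerance = 1e-3)
  expect_equal(unname(fit$coef["beta2"]), cfg$beta2, tolerance = 1e-3)
  expect_gt(goodness_of_fit(fit), 1 - 1e-6)
})

test_that("fixed-lambda fit equals direct penalized least squares (oracle)", {
  sm <- sim_model_frame(seed = 21, trees_per_site = 1, sigma_tree = 0,
                        phi = 0, germination_spread = 0)
  lam <- 2.5
  fit <- fit_growth_gamm(sm$mf, spec = growth_model_spec(
    fixed_phi = 0, fixed_tau = 0, fixed_lambda = lam, basis_dim = 8))
  expect_true(fit$converged)
  # oracle: augmented least squares solved by QR, independent of the
  # whitening/normal-equation path
  bs <- fit$basis
  X <- cbind(1, sm$mf$log_ba_prev, sm$mf$vpd_t, sm$mf$vpd_t1, bs$X)
  eS <- eigen(bs$S, symmetric = TRUE)
  sqS <- eS$vectors %*% (sqrt(pmax(eS$values, 0)) * t(eS$vectors))
  Xa <- rbind(X, cbind(matrix(0, nrow(sqS), 4), sqrt(lam) * sqS))
  beta_or <- qr.coef(qr(Xa), c(sm$mf$log_bai, rep(0, nrow(sqS))))
  expect_equal(unname(fit$coef), unname(beta_or[1:4]), tolerance = 1e-8)
  expect_equal(unname(fit$spline_coefs), unname(beta_or[-(1:4)]),
               tolerance = 1e-8)
})

test_that("AR1 whitening with known phi leaves uncorrelated residuals", {
  set.seed(9)
  phi <- 0.6
  tree <- rep(c("a", "b", "c"), each = 200)
  year <- rep(1:200, 3)
  e <- unlist(lapply(1:3, function(i) ar1_noise(200, phi)))
  aw <- ar1_whiten(matrix(e, ncol = 1), tree, year, phi)
  white <- aw$A[, 1]
  # drop the first obs of each tree (variance-scaled, not differenced)
  per_tree_acf <- vapply(c("a", "b", "c"), function(tr) {
    w <- white[tree == tr][-1]
    acf_lag1(w)
  }, numeric(1))
  expect_lt(max(abs(per_tree_acf)), 0.12)
  expect_lt(abs(mean(per_tree_acf)), 0.06)
})

test_that("estimates are exchangeable in tree order", {
  sm <- sim_model_frame(seed = 31)
  fit1 <- fit_growth_gamm(sm$mf)
  set.seed(2)
  fit2 <- fit_growth_gamm(sm$mf[sample(nrow(sm$mf)), ])
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-10)
  expect_equal(fit1$phi_hat, fit2$phi_hat, tolerance = 1e-8)
})

test_that("phi is recovered near zero when the generator has no persistence", {
  phis <- vapply(1:25, function(i) {
    sm <- sim_model_frame(seed = 100 + i, phi = 0)
    f <- fit_growth_gamm(sm$mf)
    if (isTRUE(f$converged)) f$phi_hat else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(phis, na.rm = TRUE)), 0.1)
})

test_that("doubling the innovation SD roughly halves the t statistics", {
  ratios <- vapply(1:8, function(i) {
    sm1 <- sim_model_frame(seed = 200 + i, sigma_eps = 0.25, sigma_tree = 0)
    sm2 <- sim_model_frame(seed = 200 + i, sigma_eps = 0.50, sigma_tree = 0)
    f1 <- fit_growth_gamm(sm1$mf)
    f2 <- fit_growth_gamm(sm2$mf)
    abs(f1$t["beta2"] / f2$t["beta2"])
  }, numeric(1))
  expect_gt(mean(ratios), 1.4)
  expect_lt(mean(ratios), 2.9)
})

test_that("wald tests report t = estimate/se with consistent p on the stated df", {
  sm <- sim_model_frame(seed = 41)
  fit <- fit_growth_gamm(sm$mf)
  wt <- wald_tests(fit)
  expect_setequal(wt$term, c("beta1", "beta2"))
  expect_equal(wt$t, wt$estimate / wt$se)
  expect_equal(wt$p, 2 * pt(-abs(wt$t), df = fit$df_resid))
  expect_error(wald_tests(fake_fit("S", converged = FALSE)), "converge")
})

test_that("responses are classified by sign and significance, nonconvergence propagates", {
  neg <- classify_response(fake_fit("S1", t1 = -3.1, p1 = 0.002,
                                    t2 = 2.0, p2 = 0.051))
  expect_equal(neg$class_vpd_t, "negative")
  expect_equal(neg$class_vpd_t1, "nonsignificant")  # p = 0.051 boundary
  pos <- classify_response(fake_fit("S2", t1 = 2.5, p1 = 0.01))
  expect_equal(pos$class_vpd_t, "positive")
  nc <- classify_response(fake_fit("S3", converged = FALSE))
  expect_equal(nc$class_vpd_t, "nonconvergent")
  expect_equal(nc$class_vpd_t1, "nonconvergent")
})

test_that("rank deficiency yields a nonconvergent fit, not a crash", {
  sm <- sim_model_frame(seed = 51)
  mf <- sm$mf
  mf$vpd_t <- 0.6  # constant covariate: singular design
  fit <- fit_growth_gamm(mf)
  expect_false(fit$converged)
  expect_true(is.character(fit$reason))
})

test_that("the partial-SMI variant controls for soil moisture without moving VPD effects", {
  sm <- sim_model_frame(seed = 61)
  plain <- fit_growth_gamm(sm$mf)
  partial <- fit_partial_smi_model(sm$mf)
  expect_true(partial$converged)
  expect_true(partial$include_smi)
  expect_setequal(names(partial$coef),
                  c("(Intercept)", "alpha", "beta1", "beta2", "smi1", "smi2"))
  # growth was generated with VPD only; SMI terms must not displace beta2
  expect_lt(abs(partial$coef["beta2"] - plain$coef["beta2"]),
            2 * plain$se["beta2"])
  # constant SMI is rank-deficient -> nonconvergent with reason
  mf2 <- sm$mf
  mf2$smi_t <- 70; mf2$smi_t1 <- 70
  bad <- fit_partial_smi_model(mf2)
  expect_false(bad$converged)
})

test_that("goodness of fit is the squared pooled correlation of observed and fitted", {
  sm <- sim_model_frame(seed = 71)
  fit <- fit_growth_gamm(sm$mf)
  expect_equal(goodness_of_fit(fit),
               cor(sm$mf[order(sm$mf$tree_id, sm$mf$year), "log_bai"],
                   fit$fitted)^2)
  flat <- fit
  flat$fitted <- rep(mean(fit$fitted), length(fit$fitted))
  expect_identical(goodness_of_fit(flat), 0)
})
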