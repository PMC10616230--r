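test_that("sensitivity table collects one row per significant covariate", {
  fits <- list(
    fake_fit("S1", t1 = -3, p1 = 0.01, t2 = -4, p2 = 0.001),  # both
    fake_fit("S2", t2 = -3, p2 = 0.02),                       # vpd_t1 only
    fake_fit("S3", t1 = 1, p1 = 0.4, t2 = 1, p2 = 0.6),       # none
    fake_fit("S4", converged = FALSE))                        # nonconvergent
  struct <- data.frame(site_id = c("S1", "S2", "S3", "S4"),
                       species = "PICEMAR", mean_age = 80, mean_ba = 500)
  clim <- data.frame(site_id = c("S1", "S2", "S3", "S4"), elevation = 300,
                     mat = 1, map = 800, summer_smi = 75)
  tab <- assemble_sensitivity_table(fits, struct, clim)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$which_covariate == "vpd_t1"), 2)
  expect_equal(sum(tab$which_covariate == "vpd_t"), 1)
  # no significant fits -> empty table; forest refuses clearly
  empty <- assemble_sensitivity_table(list(fits[[3]]), struct, clim)
  expect_equal(nrow(empty), 0)
  expect_error(fit_forest(empty), "response|constant")
  # missing predictor -> row dropped with a message
  clim2 <- clim; clim2$mat[1] <- NA
  expect_message(tab2 <- assemble_sensitivity_table(fits, struct, clim2),
                 "dropped")
  expect_equal(nrow(tab2), 1)
})

test_that("a single full-depth tree interpolates its training data", {
  tab <- make_sens_table(n = 5, seed = 2)
  expect_warning(fo <- fit_forest(tab, n_trees = 1, seed = 1, mtry = 7,
                                  min_node = 1), "30 rows")
  # the bootstrap resamples rows; check interpolation on the bootstrap set
  tree <- fo$trees[[1]]
  Xb <- fo$X[tree$boot, , drop = FALSE]
  expect_equal(vpdgrowth:::predict_tree(tree, Xb), fo$y[tree$boot])
})

test_that("forests and their reports are reproducible under a fixed seed", {
  tab <- make_sens_table(n = 80, seed = 3)
  f1 <- fit_forest(tab, n_trees = 60, seed = 11)
  f2 <- fit_forest(tab, n_trees = 60, seed = 11)
  expect_identical(importance_report(f1), importance_report(f2))
  expect_identical(predict(f1), predict(f2))
  f3 <- fit_forest(tab, n_trees = 60, seed = 12)
  expect_false(identical(minimal_depth_stats(f1), minimal_depth_stats(f3)))
})

test_that("an informative predictor dominates all three importance metrics", {
  tab <- make_sens_table(n = 150, seed = 5, signal = "mat", noise_sd = 0.4)
  fo <- fit_forest(tab, n_trees = 200, seed = 9)
  rep <- importance_report(fo)
  expect_equal(rep$variable[which.max(rep$mse_increase)], "mat")
  expect_equal(rep$variable[which.min(rep$avg_min_depth)], "mat")
  expect_equal(rep$variable[which.max(rep$root_node_count)], "mat")
  expect_equal(sum(rep$root_node_count), 200)
  expect_true(all(rep$avg_min_depth >= 0))
  # pure-noise predictors sit near zero importance
  noise_imp <- rep$mse_increase[rep$variable == "elevation"]
  expect_lt(abs(noise_imp), 0.15 * max(rep$mse_increase))
  # out-of-bag error beats the null model on informative data
  oob_pred <- oob_predictions(fo)
  ok <- !is.na(oob_pred)
  expect_lt(mean((fo$y[ok] - oob_pred[ok])^2), var(fo$y))
})

test_that("duplicating a predictor splits its importance between the copies", {
  tab <- make_sens_table(n = 150, seed = 6, signal = "mat", noise_sd = 0.3)
  solo <- importance_report(fit_forest(tab, n_trees = 150, seed = 4))
  tab$mat2 <- tab$mat
  dup <- importance_report(fit_forest(
    tab, n_trees = 150, seed = 4,
    predictors = c("elevation", "mat", "map", "summer_smi", "species",
                   "mean_age", "mean_ba", "mat2")))
  solo_mat <- solo$mse_increase[solo$variable == "mat"]
  dup_mat <- dup$mse_increase[dup$variable == "mat"]
  dup_mat2 <- dup$mse_increase[dup$variable == "mat2"]
  expect_gt(dup_mat2, 0)
  expect_lt(dup_mat, solo_mat)
  expect_lt(dup_mat2, solo_mat)
})

test_that("partial dependence is flat for a stump-less forest and tracks monotone signals", {
  tab <- make_sens_table(n = 80, seed = 7)
  # min_node larger than n: every tree is a single leaf -> constant model
  flat <- fit_forest(tab, n_trees = 20, seed = 2, min_node = 1000)
  pd <- partial_dependence(flat, "mat")
  expect_lt(diff(range(pd$pd)), 1e-12)
  # response rising in mean_age -> non-decreasing PD curve (edge tolerance)
  tab2 <- make_sens_table(n = 150, seed = 8, signal = "mean_age",
                          noise_sd = 0.3)
  tab2$t_value <- -tab2$t_value  # increasing in mean_age
  fo <- fit_forest(tab2, n_trees = 150, seed = 5)
  pd2 <- partial_dependence(fo, "mean_age")
  expect_gt(cor(pd2$value, pd2$pd), 0.9)
  expect_gt(pd2$pd[nrow(pd2)], pd2$pd[1])
  expect_length(attr(pd2, "coverage95"), 2)
  expect_warning(partial_dependence(fo, "mean_age", grid = c(0, 500)),
                 "outside")
})

test_that("categorical species yields one PD value per level, order-invariant", {
  tab <- make_sens_table(n = 100, seed = 9, signal = "species")
  fo <- fit_forest(tab, n_trees = 80, seed = 3)
  pd <- partial_dependence(fo, "species")
  expect_equal(sort(pd$value), sort(unique(tab$species)))
  set.seed(1)
  fo2 <- fit_forest(tab[sample(nrow(tab)), ], n_trees = 80, seed = 3)
  pd2 <- partial_dependence(fo2, "species")
  expect_equal(pd2$value, pd$value)  # level order fixed by sorted levels
})
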