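# Non-electrostatic models, electrostatic rescaling, prediction and scoring.

test_that("frozen model constants and intercept correction are consistent", {
  expect_equal(eval_non_es(pb_original_model(), 0), 1.09)
  expect_equal(eval_non_es(pb_modified_model(), 0), 4.92)
  expect_equal(corrected_intercept(3.56, 1.36), 4.92)
  expect_equal(corrected_intercept(3.56, 1.65), 5.21)
  expect_equal(corrected_intercept(2.7, 0), 2.7)

  # the frozen modified model IS the corrected line at every surface area
  for (asa in c(0, 57.3, 240, 375.6, 450)) {
    expect_equal(eval_non_es(pb_modified_model(), asa),
                 corrected_intercept(3.56, 1.36) + (-0.0131) * asa,
                 tolerance = 1e-12)
  }
  root <- 4.92 / 0.0131
  expect_equal(eval_non_es(pb_modified_model(), root), 0, tolerance = 1e-12)
  expect_error(eval_non_es(pb_modified_model(), -1), ">= 0")
})

test_that("electrostatic rescale between LRT coefficients is exact and invertible", {
  expect_equal(rescale_es(-5, 0.5, 0.41), -4.1)
  expect_equal(rescale_es(-3.7, 0.5, 0.5), -3.7)
  x <- c(-9.4, -1.2, 0, 2.2)
  expect_equal(rescale_es(rescale_es(x, 0.5, 0.41), 0.41, 0.5), x,
               tolerance = 1e-12)
  expect_error(rescale_es(-5, 0, 0.41), "nonzero")
})

test_that("predictions compose exactly and reduce correctly in edge cases", {
  flat <- solute_table("only_non_es", e_reorg = 0, dA_es = 0, dA_disp = -1,
                       dA_cav = 1, asa = 300)
  p <- predict_hydration(flat, pb_modified_model())
  expect_equal(p$dA_hyd_pred, eval_non_es(pb_modified_model(), 300))

  # benzene components with the non-ES part forced to its tabulated value
  benz <- solute_table("benzene_like", e_reorg = 0.35, dA_es = -1.14,
                       dA_disp = -9.66, dA_cav = 9.32, asa = 123.4)
  forced <- non_es_model(0, -0.34, "forced")
  expect_equal(predict_hydration(benz, forced)$dA_hyd_pred, -1.13,
               tolerance = 1e-12)

  # linearity: doubling all inputs doubles the output under a pure-slope model
  lin <- non_es_model(-0.01, 0, "lin")
  one <- predict_hydration(benz, lin)
  doubled <- solute_table("benzene_like", 0.70, -2.28, -19.32, 18.64,
                          asa = 246.8)
  expect_equal(predict_hydration(doubled, lin)$dA_hyd_pred,
               2 * one$dA_hyd_pred, tolerance = 1e-12)

  # the composed total is exactly the sum of its three reported addends
  set.seed(5)
  tab <- solute_table(sprintf("s%d", 1:30), runif(30, 0.3, 0.9),
                      runif(30, -4, -1), runif(30, -20, -9),
                      runif(30, 9, 18), asa = runif(30, 200, 450))
  p2 <- predict_hydration(tab, pb_modified_model(), es_mode = "rescaled")
  expect_identical(p2$dA_hyd_pred,
                   p2$e_reorg + p2$dA_es_used + p2$dA_non_es_used)
  expect_equal(p2$dA_es_used, tab$dA_es * 0.82, tolerance = 1e-12)

  no_asa <- solute_table("x", 0.3, -1, -9, 9)
  expect_error(predict_hydration(no_asa, pb_modified_model()), "asa")
})

test_that("MAE/RMSE scoring matches hand arithmetic and its invariances", {
  s <- score_predictions(c(1, 2), c(2, 0))
  expect_equal(s$mae, 1.5)
  expect_equal(s$rmse, sqrt(2.5))

  ident <- score_predictions(c(-1.1, 2.2), c(-1.1, 2.2))
  expect_equal(c(ident$mae, ident$rmse), c(0, 0))

  set.seed(11)
  a <- rnorm(40); b <- rnorm(40)
  base <- score_predictions(a, b)
  expect_lte(base$mae, base$rmse)
  perm <- sample(40)
  shuffled <- score_predictions(a[perm], b[perm])
  expect_equal(shuffled$mae, base$mae)
  expect_equal(shuffled$rmse, base$rmse)
  shifted <- score_predictions(a + 3.7, b + 3.7)
  expect_equal(shifted$rmse, base$rmse, tolerance = 1e-12)

  expect_error(score_predictions(1:3, 1:2), "length")
})

test_that("refit recovers generator coefficients from synthetic records", {
  cfg <- generator_config(n_solutes = 50, seed = 7, component_noise_sd = 0.1)
  recs <- generate_solute_set(cfg)$records
  model <- refit_non_es(recs)
  net_slope <- cfg$disp_slope + cfg$cav_slope
  net_intercept <- cfg$disp_intercept + cfg$cav_intercept
  expect_lt(abs(model$slope - net_slope), 0.002)
  expect_lt(abs(model$intercept - net_intercept), 0.5)

  # noise-free records recover the line exactly
  clean <- generate_solute_set(generator_config(n_solutes = 20, seed = 3,
                                                component_noise_sd = 0,
                                                lrt_noise_sd = 0,
                                                exp_noise_sd = 0))$records
  exact <- refit_non_es(clean)
  expect_equal(exact$slope, net_slope, tolerance = 1e-10)
  expect_equal(exact$intercept, net_intercept, tolerance = 1e-10)

  flat <- solute_table(c("a", "b", "c"), 0.5, -1, c(-9, -10, -11),
                       c(9, 10, 11), asa = 300)
  expect_error(refit_non_es(flat), "constant")
})

test_that("refit plus predict achieves RMSE commensurate with injected noise", {
  cfg <- generator_config(n_solutes = 300, seed = 21)
  recs <- generate_solute_set(cfg)$records
  model <- refit_non_es(recs)
  preds <- predict_hydration(recs, model)
  rmse <- score_predictions(preds$dA_hyd_pred, recs$exp_dA_hyd)$rmse
  # prediction uses dA_es as given, so the residual noise is the two
  # component channels plus the experimental channel
  sigma <- sqrt(2 * cfg$component_noise_sd^2 + cfg$exp_noise_sd^2)
  expect_gt(rmse, 0.5 * sigma)
  expect_lt(rmse, 2 * sigma)
})
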