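small_experiment_inputs <- function(n = 30, m = 120, h2 = 0.8, seed = 91) {
  cfg <- sim_config(n_cultivars = n, n_markers = m, n_qtl = 25,
                    target_h2 = h2, n_grains_per_cultivar = 100,
                    seed = seed)
  codes <- simulate_markers(cfg)
  truth <- simulate_distribution_params(codes, cfg)
  list(codes = codes, params = truth$params)
}

test_that("the accuracy report has the expected trait rows and schema", {
  inp <- small_experiment_inputs()
  exp <- run_prediction_experiment(inp$codes, inp$params,
                                   schemes = c("gblup", "pls3"),
                                   max_ncomp = 5, select = "global")
  expect_s3_class(exp, "prediction_experiment")
  expect_named(exp$schemes, c("gblup", "pls3"))
  rows <- exp$schemes$gblup$accuracies$trait
  expect_equal(rows, c("p", "a1", "b1", "a2", "b2", "mode1", "skewness1",
                       "mu2", "var2", "boundary_point",
                       "boundary_probability", "p23mg", "p90pct",
                       "sink_filling_rate"))
  # parenthesized (direct) route present for GBLUP only
  expect_true("prediction_direct" %in% names(exp$schemes$gblup$accuracies))
  expect_false("prediction_direct" %in% names(exp$schemes$pls3$accuracies))
  vc <- exp$schemes$gblup$variance_components
  expect_true(all(c("p", "mode1", "skewness1", "mu2", "var2") %in% vc$trait))
  expect_true(all(vc$h2 >= 0 & vc$h2 <= 1))
  # 3-group scheme selected components for three models
  expect_equal(names(exp$schemes$pls3$ncomp), c("p", "left", "right"))
  # JSON report round-trips with the documented keys
  path <- tempfile(fileext = ".json")
  write_report_json(exp, path)
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_named(rep, c("n_cultivars", "n_markers", "schemes"))
  expect_named(rep$schemes$gblup[c("press_fitting", "q2_fitting",
                                   "press_prediction", "q2_prediction")],
               c("press_fitting", "q2_fitting", "press_prediction",
                 "q2_prediction"))
})

test_that("injecting observed parameters as predictions gives a perfect score", {
  inp <- small_experiment_inputs(n = 15, m = 60, seed = 92)
  obs <- inp$params
  ps <- prediction_set(obs, obs)
  expect_equal(press(ps), 0, tolerance = 1e-10)
  expect_equal(q2_shape(ps), 1, tolerance = 1e-10)
  for (pc in c("p", "a1", "b1", "a2", "b2"))
    expect_equal(cor(obs[[pc]], obs[[pc]]), 1)
})

test_that("heritable signal yields positive prediction accuracy", {
  inp <- small_experiment_inputs(n = 60, m = 200, h2 = 0.9, seed = 93)
  exp <- run_prediction_experiment(inp$codes, inp$params,
                                   schemes = "gblup")
  acc <- exp$schemes$gblup$accuracies
  expect_gt(acc$prediction[acc$trait == "mu2"], 0)
  expect_gt(acc$prediction[acc$trait == "p"], 0)
  expect_true(all(acc$fitting[1:5] > acc$prediction[1:5] - 0.05))
})

test_that("one-group and three-group PLS concur on the dominant right component", {
  # a2 dominates the unscaled response variance, so the score spaces of the
  # all-parameter model and the right-component model nearly coincide
  inp <- small_experiment_inputs(n = 50, m = 150, h2 = 0.9, seed = 94)
  X <- inp$codes
  Yall <- as.matrix(inp$params[, c("p", "a1", "b1", "a2", "b2")])
  Yright <- as.matrix(inp$params[, c("a2", "b2")])
  k <- 3
  f1 <- pls_fit(X, Yall, ncomp = k)
  f3 <- pls_fit(X, Yright, ncomp = k)
  p1 <- predict(f1, X, ncomp = k)[, c("a2", "b2")]
  p3 <- predict(f3, X, ncomp = k)
  expect_gt(cor(p1[, "a2"], p3[, "a2"]), 0.99)
  expect_gt(cor(p1[, "b2"], p3[, "b2"]), 0.99)
})

test_that("per-fold and global component selection both produce predictions", {
  inp <- small_experiment_inputs(n = 20, m = 80, seed = 95)
  exp <- run_prediction_experiment(inp$codes, inp$params, schemes = "plsE",
                                   max_ncomp = 3, select = "per-fold")
  pred <- exp$schemes$plsE$predicted
  expect_false(any(is.na(pred[, c("p", "a1", "b1", "a2", "b2")])))
  expect_equal(nrow(pred), 20)
})

test_that("cultivar alignment failures are reported", {
  inp <- small_experiment_inputs(n = 15, m = 60, seed = 96)
  params <- rbind(inp$params,
                  data.frame(cultivar_id = "ghost", p = 0.2, a1 = 1.5,
                             b1 = 4, a2 = 100, b2 = 0.25))
  expect_warning(run_prediction_experiment(inp$codes, params,
                                           schemes = "gblup"),
                 "ghost")
  expect_error(run_prediction_experiment(inp$codes[1:5, ], inp$params[1:5, ],
                                         schemes = "gblup"),
               ">= 10")
})
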