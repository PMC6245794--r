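make_sample <- function(n = 2000, params = mixture_params(0.2, 1.5, 4,
                                                          100, 0.25),
                        seed = 1) {
  simulate_grain_weights(params, n, seed = seed)$weights
}

test_that("initial parameters follow the moment-matched construction", {
  w <- make_sample(500, seed = 5)
  v <- var(w)
  set.seed(7)
  init <- init_parameters(grain_sample(w))
  expect_equal(init$p, 0.5)
  # each initial component mean a0*b0 equals a sampled weight x', with
  # a0 = x'^2 / Var(x) and b0 = Var(x) / x'
  for (side in list(c(init$a1, init$b1), c(init$a2, init$b2))) {
    xprime <- side[1] * side[2]
    expect_true(any(abs(w - xprime) < 1e-12))
    expect_equal(side[1], xprime^2 / v, tolerance = 1e-12)
    expect_equal(side[2], v / xprime, tolerance = 1e-12)
  }
  # lighter draw seeds the left component
  expect_lte(init$a1 * init$b1, init$a2 * init$b2)
  # direct substitution: Var = 4, x' = 2 gives a0 = 1, b0 = 2
  expect_equal(2^2 / 4, 1)
  expect_equal(4 / 2, 2)
  # seeded reproducibility
  set.seed(7)
  init2 <- init_parameters(grain_sample(w))
  expect_identical(init, init2)
})

test_that("EM increases the log-likelihood monotonically and labels canonically", {
  w <- make_sample(1500, seed = 2)
  set.seed(3)
  for (i in 1:3) {
    fit <- em_fit(grain_sample(w), init_parameters(grain_sample(w)))
    expect_true(all(diff(fit$loglik_trace) > -1e-9))
    expect_lte(fit$params$a1 * fit$params$b1,
               fit$params$a2 * fit$params$b2)
    expect_true(fit$converged)
  }
})

test_that("EM recovers known parameters from a large sample", {
  truth <- mixture_params(0.2, 1.5, 4, 100, 0.25)
  w <- make_sample(4000, truth, seed = 4)
  fit <- fit_with_restarts(grain_sample(w), n_restarts = 10, seed = 6)
  expect_equal(fit$params$p, truth$p, tolerance = 0.02)
  mu2_hat <- fit$params$a2 * fit$params$b2
  expect_equal(mu2_hat / (truth$a2 * truth$b2), 1, tolerance = 0.02)
})

test_that("multi-restart fit is deterministic and returns the argmax", {
  w <- make_sample(800, seed = 8)
  f1 <- fit_with_restarts(grain_sample(w), n_restarts = 8, seed = 42)
  f2 <- fit_with_restarts(grain_sample(w), n_restarts = 8, seed = 42)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$restart_index, f2$restart_index)
  expect_gte(f1$loglik, max(f1$restart_logliks, na.rm = TRUE) - 1e-9)
})

test_that("restarts agree on well-separated data", {
  w <- make_sample(2000, mixture_params(0.25, 1.5, 3, 120, 0.21), seed = 10)
  fit <- fit_with_restarts(grain_sample(w), n_restarts = 100, seed = 11)
  agree <- sum(abs(fit$restart_logliks - fit$loglik) < 1e-6, na.rm = TRUE)
  expect_gte(agree, 95)
})

test_that("sample preparation enforces the floor and minimum size", {
  w <- c(rep(0, 20), runif(100, 5, 30))
  s <- grain_sample(w, "cv1")
  expect_equal(s$n_excluded_zero, 20)
  expect_true(all(s$weights > 0.1))
  expect_error(grain_sample(runif(10, 5, 30)), "minimum")
  expect_error(init_parameters(grain_sample(rep(10, 60), min_grains = 50)),
               "variance")
})

test_that("fit_cultivars pools, fits, and flags failures", {
  set.seed(12)
  truth <- list(cv1 = mixture_params(0.15, 1.5, 4, 100, 0.25),
                cv2 = mixture_params(0.3, 2, 3, 80, 0.3))
  df <- do.call(rbind, lapply(names(truth), function(id) {
    data.frame(cultivar_id = id, panicle_id = rep(c("p1", "p2"), each = 400),
               grain_weight_mg = simulate_grain_weights(truth[[id]], 800,
                                                        seed = match(id, names(truth)))$weights)
  }))
  # one cultivar with too few grains must be flagged, not dropped silently
  df <- rbind(df, data.frame(cultivar_id = "tiny", panicle_id = "p1",
                             grain_weight_mg = runif(10, 10, 30)))
  expect_warning(res <- fit_cultivars(df, n_restarts = 5, seed = 1),
                 "tiny")
  expect_equal(nrow(res$table), 3)
  expect_false(res$table$converged[res$table$cultivar_id == "tiny"])
  ok <- res$table[res$table$cultivar_id != "tiny", ]
  expect_true(all(ok$converged))
  expect_equal(ok$p, c(0.15, 0.3), tolerance = 0.08)
  expect_null(res$fits[["tiny"]])
})
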