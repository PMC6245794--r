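test_that("gamma self-energy matches its closed form identities", {
  for (beta in c(0.3, 1, 4))
    expect_equal(g_term(1, beta), 1 / (2 * beta), tolerance = 1e-12)
  expect_equal(g_term(3, 2 * 1.5), g_term(3, 1.5) / 2, tolerance = 1e-12)
  expect_equal(g_term(2.5, 3), quad_g(2.5, 3), tolerance = 1e-8)
  expect_error(g_term(0.5, 1), "diverges")
  expect_error(g_term(0.3, 1), "diverges")
})

test_that("gamma cross-energy is symmetric and reduces to the self-energy", {
  expect_equal(h_term(3, 3, 1.5, 1.5), 2 * g_term(3, 1.5), tolerance = 1e-12)
  expect_equal(h_term(2, 3, 1.5, 0.7), h_term(3, 2, 0.7, 1.5),
               tolerance = 1e-12)
  expect_equal(h_term(2, 3, 1.5, 0.7), quad_h(2, 3, 1.5, 0.7),
               tolerance = 1e-8)
  expect_error(h_term(0.4, 0.5, 1, 1), "diverges")
})

test_that("energy terms agree with quadrature over a random sweep", {
  set.seed(51)
  for (i in 1:30) {
    a <- exp(runif(2, log(0.6), log(200)))
    b <- exp(runif(2, log(0.01), log(10)))
    expect_equal(g_term(a[1], b[1]), quad_g(a[1], b[1]),
                 tolerance = 1e-8)
    expect_equal(h_term(a[1], a[2], b[1], b[2]),
                 quad_h(a[1], a[2], b[1], b[2]), tolerance = 1e-8)
  }
})

test_that("squared L2 distance is a squared metric", {
  f <- mixture_params(0.2, 1.5, 4, 100, 0.25)
  g <- mixture_params(0.3, 2, 3, 80, 0.3)
  expect_equal(squared_l2_distance(f, f), 0, tolerance = 1e-10)
  expect_equal(squared_l2_distance(f, g), squared_l2_distance(g, f),
               tolerance = 1e-12)
  expect_gte(squared_l2_distance(f, g), 0)
  expect_error(squared_l2_distance(mixture_params(0.2, 0.45, 4, 100, 0.25),
                                   g), "shape")
})

test_that("squared L2 distance matches quadrature on random pairs", {
  set.seed(52)
  for (i in 1:20) {
    f <- rand_mixture(); g <- rand_mixture()
    d <- squared_l2_distance(f, g)
    expect_equal(d, quad_l2(f, g), tolerance = 1e-6 * max(d, 1e-10))
  }
})

test_that("PRESS sums per-cultivar squared distances", {
  set.seed(53)
  obs <- replicate(3, rand_grain_mixture(), simplify = FALSE)
  names(obs) <- paste0("cv", 1:3)
  pred <- lapply(obs, function(m)
    mixture_params(min(m$p * 1.1, 1), m$a1 * 0.9, m$b1 * 1.1,
                   m$a2 * 1.05, m$b2 * 0.95))
  ps <- prediction_set(obs, pred)
  expect_equal(press(ps),
               sum(mapply(squared_l2_distance, obs, pred)),
               tolerance = 1e-12)
  # identical prediction: zero
  expect_equal(press(prediction_set(obs, obs)), 0, tolerance = 1e-12)
  # single cultivar reduces to the distance itself
  ps1 <- prediction_set(obs[1], pred[1])
  expect_equal(press(ps1), squared_l2_distance(obs[[1]], pred[[1]]))
  # alignment errors are caught
  bad <- pred; names(bad)[1] <- "zz"
  expect_error(prediction_set(obs, bad), "differ")
})

test_that("Q2 is calibrated against the mean-parameter predictor", {
  set.seed(54)
  obs <- replicate(5, rand_grain_mixture(), simplify = FALSE)
  names(obs) <- paste0("cv", 1:5)
  ps_perfect <- prediction_set(obs, obs)
  expect_equal(q2_shape(ps_perfect), 1, tolerance = 1e-10)
  ref <- ps_perfect$reference_means
  ps_mean <- prediction_set(obs, setNames(rep(list(ref), 5), names(obs)))
  expect_equal(q2_shape(ps_mean), 0, tolerance = 1e-10)
  # a predictor worse than the mean goes negative, unclamped: observed
  # population nearly homogeneous (small denominator) but predictions far
  tight <- lapply(1:5, function(i)
    mixture_params(0.2 + 0.001 * i, 1.5, 4, 100, 0.25 + 1e-4 * i))
  names(tight) <- paste0("t", 1:5)
  far <- lapply(tight, function(m)
    mixture_params(m$p, m$a1, m$b1, m$a2, m$b2 * 2))
  expect_lt(q2_shape(prediction_set(tight, far)), 0)
})

test_that("Q2 agrees with a fully quadrature-based evaluation", {
  set.seed(55)
  obs <- replicate(3, rand_grain_mixture(), simplify = FALSE)
  names(obs) <- paste0("cv", 1:3)
  pred <- lapply(obs, function(m)
    mixture_params(m$p * 0.9, m$a1 * 1.2, m$b1 * 0.85, m$a2 * 0.95,
                   m$b2 * 1.08))
  ps <- prediction_set(obs, pred)
  num <- sum(mapply(quad_l2, obs, pred))
  den <- sum(vapply(obs, quad_l2, numeric(1),
                    f_hat = ps$reference_means))
  expect_equal(q2_shape(ps), 1 - num / den, tolerance = 1e-6)
})
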