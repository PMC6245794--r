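test_that("marker simulation honours the inbred contract and seed", {
  cfg <- sim_config(n_cultivars = 60, n_markers = 150, seed = 101)
  codes <- simulate_markers(cfg)
  expect_equal(dim(codes), c(60, 150))
  expect_true(all(codes %in% c(-1, 1)))
  expect_identical(codes, simulate_markers(cfg))
  # heterozygosity knob produces 0 codes
  cfg_het <- sim_config(n_cultivars = 60, n_markers = 150, het_rate = 0.2,
                        seed = 101)
  expect_gt(mean(simulate_markers(cfg_het) == 0), 0.1)
  # duplicate columns exercise the linkage filter
  cfg_dup <- sim_config(n_cultivars = 60, n_markers = 150,
                        n_duplicate_markers = 10, seed = 101)
  dup <- simulate_markers(cfg_dup)
  expect_equal(ncol(dup), 160)
  expect_gte(attr(filter_markers(dup), "filter_counts")["duplicate"], 10)
})

test_that("simulated parameters are valid mixtures with tunable heritability", {
  cfg <- sim_config(n_cultivars = 300, n_markers = 400, n_qtl = 40,
                    target_h2 = 0.6, n_grains_per_cultivar = 100,
                    seed = 102)
  codes <- simulate_markers(cfg)
  truth <- simulate_distribution_params(codes, cfg)
  pars <- truth$params
  expect_true(all(pars$p >= 0 & pars$p <= 1))
  expect_true(all(pars$a1 > 0 & pars$b1 > 0 & pars$a2 > 0 & pars$b2 > 0))
  expect_true(all(pars$a1 * pars$b1 < pars$a2 * pars$b2))
  # realized latent-scale heritability near the target, averaged over reps
  h2_hat <- replicate(10, {
    seed <- sample.int(1e6, 1)
    cfgr <- sim_config(n_cultivars = 300, n_markers = 400, n_qtl = 40,
                       target_h2 = 0.6, n_grains_per_cultivar = 100,
                       seed = seed)
    cd <- simulate_markers(cfgr)
    tr <- simulate_distribution_params(cd, cfgr)
    u <- tr$genetic_values[, "a2"]
    latent <- log(tr$params$a2)
    var(u) / var(latent)
  })
  expect_equal(mean(h2_hat), 0.6, tolerance = 0.1)
})

test_that("zero-signal configuration yields uncorrelated parameters", {
  cfg <- sim_config(n_cultivars = 100, n_markers = 200, n_qtl = 30,
                    target_h2 = 0.01, n_grains_per_cultivar = 100,
                    seed = 103)
  codes <- simulate_markers(cfg)
  truth <- simulate_distribution_params(codes, cfg)
  # true genetic values are a negligible share of the latent variance
  expect_lt(var(truth$genetic_values[, "p"]) /
              var(qlogis(truth$params$p)), 0.05)
})

test_that("grain weight sampling matches the mixture moments", {
  mp <- mixture_params(0.2, 1.5, 4, 100, 0.25)
  gw <- simulate_grain_weights(mp, 1e5, seed = 104)
  expect_true(all(gw$weights > 0))
  expect_equal(mean(gw$weights), mixture_mean(mp), tolerance = 0.01)
  expect_equal(mean(gw$component == 1), mp$p, tolerance = 0.01)
  # membership labels are faithful: left-component draws are lighter
  expect_lt(mean(gw$weights[gw$component == 1]),
            mean(gw$weights[gw$component == 2]))
  expect_identical(gw, simulate_grain_weights(mp, 1e5, seed = 104))
})

test_that("make_dataset composes generators deterministically", {
  cfg <- sim_config(n_cultivars = 8, n_markers = 50, n_qtl = 10,
                    n_grains_per_cultivar = 300, seed = 105)
  ds <- make_dataset(cfg)
  expect_equal(dim(ds$codes), c(8, 50))
  expect_equal(length(ds$samples), 8)
  expect_equal(nrow(ds$grain_data), 8 * 300)
  expect_identical(ds$params, make_dataset(cfg)$params)
  expect_identical(ds$samples, make_dataset(cfg)$samples)
})

test_that("the fitting pipeline recovers the simulated mixing proportion", {
  cfg <- sim_config(n_cultivars = 8, n_markers = 50, n_qtl = 10,
                    n_grains_per_cultivar = 2000, seed = 106)
  ds <- make_dataset(cfg)
  err <- vapply(names(ds$samples), function(id) {
    fit <- fit_with_restarts(grain_sample(ds$samples[[id]]),
                             n_restarts = 8, seed = 107)
    abs(fit$params$p - ds$params$p[ds$params$cultivar_id == id])
  }, numeric(1))
  expect_lt(median(err), 0.03)
})
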