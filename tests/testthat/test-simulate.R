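test_that("regime paths follow the chain: frequencies, occupancy, sojourns", {
  params <- ms_preset("refrescos")
  cfg <- sim_config(params, n_months = 10000, seed = 2014)
  s <- simulate_regime_path(cfg)
  expect_true(all(s %in% 1:2))

  # empirical transition frequencies close to P
  from <- s[-length(s)]; to <- s[-1]
  p11_hat <- mean(to[from == 1] == 1)
  p22_hat <- mean(to[from == 2] == 2)
  expect_lt(abs(p11_hat - params$p11), 0.01)
  expect_lt(abs(p22_hat - params$p22), 0.01)

  # ergodic occupancy close to the stationary distribution
  expect_lt(abs(mean(s == 1) - stationary_distribution(params$p11, params$p22)[["low"]]),
            0.02)

  # mean sojourn lengths near 1/(1 - p_stay), within 10%
  r <- rle(s)
  for (st in 1:2) {
    expected <- expected_duration(if (st == 1) params$p11 else params$p22)
    observed <- mean(r$lengths[r$values == st])
    expect_lt(abs(observed - expected) / expected, 0.10)
  }
})

test_that("absorbing chain stays put", {
  params <- ms_params(1, 0.5, mu = c(0, 0.1), sigma = 0.01)
  cfg <- sim_config(params, n_months = 50, seed = 1, init_state = "low")
  expect_true(all(simulate_regime_path(cfg) == 1L))
})

test_that("simulation is seed-deterministic and noise-path separable", {
  params <- ms_preset("pan_dulce")
  a <- simulate_inflation(sim_config(params, 120, seed = 5))
  b <- simulate_inflation(sim_config(params, 120, seed = 5))
  expect_identical(as.numeric(a), as.numeric(b))
  c <- simulate_inflation(sim_config(params, 120, seed = 6))
  expect_false(identical(as.numeric(a), as.numeric(c)))

  # same root seed, different sigma: identical regime path
  bumped <- ms_params(params$p11, params$p22, params$mu, params$sigma * 3)
  d <- simulate_inflation(sim_config(bumped, 120, seed = 5))
  expect_identical(attr(a, "regimes"), attr(d, "regimes"))
})

test_that("noiseless simulation equals the regime means exactly", {
  params <- ms_params(0.9, 0.8, mu = c(0.02, 0.15), sigma = 0)
  cfg <- sim_config(params, 60, seed = 3)
  y <- simulate_inflation(cfg)
  s <- simulate_regime_path(cfg)
  expect_identical(as.numeric(y), params$mu[s])
})

test_that("per-regime sample means recover the preset conditional means", {
  params <- ms_preset("refrescos")
  y <- simulate_inflation(sim_config(params, 5000, seed = 2014))
  s <- attr(y, "regimes")
  expect_lt(abs(mean(y[s == 1]) - params$mu[1]), 0.001)
  expect_lt(abs(mean(y[s == 2]) - params$mu[2]), 0.001)
})

test_that("CPI reconstruction inverts the inflation transform exactly", {
  set.seed(31)
  y <- inflation_series(rnorm(72, 0.05, 0.04), start = c(2010, 1))
  cpi <- simulate_cpi_from_inflation(y, base_index = 100)
  expect_length(cpi, 84)
  expect_equal(start(cpi), c(2009, 1))
  back <- annualized_inflation(cpi)
  expect_equal(as.numeric(back), as.numeric(y), tolerance = 1e-12)
  expect_equal(start(back), c(2010, 1))

  # constant 5% inflation from base 100: second year of the index is 105
  y5 <- inflation_series(rep(0.05, 24))
  cpi5 <- simulate_cpi_from_inflation(y5, base_index = 100)
  expect_equal(as.numeric(cpi5)[13:24], rep(105, 12))
  expect_equal(as.numeric(simulate_cpi_from_inflation(inflation_series(rep(0, 24)))),
               rep(100, 36))
})

test_that("presets carry the printed estimates and reject unknown names", {
  r <- ms_preset("refrescos")
  expect_equal(r$p11, 0.9853)
  expect_equal(r$p22, 0.9064)
  expect_equal(r$mu, c(0.0326, 0.1494))
  expect_equal(r$sigma, 0.0059)

  a <- ms_preset("azucar")
  expect_equal(a$mu, c(-0.2009, 0.1446))
  expect_equal(a$sigma, 0.0973)

  g <- ms_preset("gelatina")
  expect_equal(g$sigma, c(0.0010, 0.0192))

  tab <- ms_presets()
  expect_equal(nrow(tab), 19)
  expect_equal(sum(tab$switching_variance), 5)
  expect_true(all(tab$mu_low < tab$mu_high))

  expect_error(ms_preset("unknown"), "refrescos")
})

test_that("simulation configs load from YAML and JSON", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("preset: refrescos", "n_months: 24", "seed: 9"), yml)
  cfg <- read_sim_config(yml)
  expect_equal(cfg$n_months, 24L)
  expect_equal(cfg$params$p11, 0.9853)

  js <- tempfile(fileext = ".json")
  writeLines('{"params": {"p11": 0.9, "p22": 0.8, "mu": [0.01, 0.1],
               "sigma": [0.02]}, "n_months": 12, "seed": 2}', js)
  cfg2 <- read_sim_config(js)
  expect_equal(cfg2$params$mu, c(0.01, 0.1))
  expect_identical(as.numeric(simulate_inflation(cfg2)),
                   as.numeric(simulate_inflation(cfg2)))
})
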