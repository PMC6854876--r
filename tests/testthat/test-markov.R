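test_that("filter log-likelihood matches path enumeration across random models", {
  set.seed(42)
  for (i in 1:30) {
    sw <- i %% 2 == 0
    ar <- i %% 3          # exercises AR(0), AR(1) and AR(2) joint states
    params <- random_valid_params(sw, ar)
    Tn <- sample(3:12, 1)
    y <- inflation_series(rnorm(Tn, mean(params$mu), 0.05))
    ll_f <- hamilton_filter(y, params)$loglik
    ll_b <- brute_force_loglik(y, params)
    expect_equal(ll_f, ll_b, tolerance = 1e-8)
  }
})

test_that("indistinguishable regimes collapse to the i.i.d. Gaussian likelihood", {
  set.seed(8)
  y <- rnorm(40, 0.05, 0.02)
  for (p11 in c(0.5, 0.9, 0.99)) {
    params <- ms_params(p11, runif(1, 0.3, 0.95), mu = c(0.04, 0.04), sigma = 0.02)
    expect_equal(hamilton_filter(y, params)$loglik,
                 sum(dnorm(y, 0.04, 0.02, log = TRUE)), tolerance = 1e-10)
  }
})

test_that("independence limit: p11 = p22 = 0.5 gives a per-month mixture", {
  set.seed(9)
  params <- ms_params(0.5, 0.5, mu = c(0.01, 0.12), sigma = c(0.02, 0.04))
  y <- rnorm(10, 0.05, 0.05)
  mix <- sum(log(0.5 * dnorm(y, 0.01, 0.02) + 0.5 * dnorm(y, 0.12, 0.04)))
  expect_equal(hamilton_filter(y, params)$loglik, mix, tolerance = 1e-10)
  expect_equal(brute_force_loglik(y, params), mix, tolerance = 1e-8)
})

test_that("filtered and predicted probabilities are normalized", {
  set.seed(10)
  params <- random_valid_params(TRUE, 1L)
  y <- inflation_series(rnorm(60, 0.05, 0.03))
  pr <- hamilton_filter(y, params)$probs
  expect_equal(rowSums(pr$filtered), rep(1, nrow(pr$filtered)), tolerance = 1e-10)
  expect_equal(rowSums(pr$predicted), rep(1, nrow(pr$predicted)), tolerance = 1e-10)
  expect_true(all(pr$filtered >= 0 & pr$filtered <= 1))
})

test_that("Kim smoother reproduces brute-force posterior marginals", {
  set.seed(14)
  for (i in 1:10) {
    sw <- i %% 2 == 0
    ar <- i %% 2
    params <- random_valid_params(sw, ar)
    Tn <- sample((ar + 2):10, 1)
    y <- inflation_series(rnorm(Tn, mean(params$mu), 0.04))
    pr <- kim_smoother(hamilton_filter(y, params)$probs, params)
    post <- brute_force_posterior(y, params)
    # smoother covers months ar+1 .. T of the series
    expect_equal(unname(pr$smoothed),
                 unname(post[(ar + 1):Tn, , drop = FALSE]), tolerance = 1e-8)
    expect_equal(rowSums(pr$smoothed), rep(1, nrow(pr$smoothed)), tolerance = 1e-10)
    # last month: no future information, smoothed equals filtered
    n <- nrow(pr$smoothed)
    expect_equal(pr$smoothed[n, ], pr$filtered[n, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("single-month series: smoothed equals filtered, mixture closed form", {
  params <- ms_params(0.8, 0.7, mu = c(0.0, 0.1), sigma = 0.03)
  pr <- kim_smoother(hamilton_filter(0.05, params)$probs, params)
  expect_equal(pr$smoothed, pr$filtered)
  w <- stationary_distribution(0.8, 0.7)
  expect_equal(hamilton_filter(0.05, params)$loglik,
               log(w[["low"]] * dnorm(0.05, 0, 0.03) +
                   w[["high"]] * dnorm(0.05, 0.1, 0.03)))
})

test_that("relabelling the states leaves the likelihood unchanged", {
  set.seed(21)
  for (i in 1:8) {
    params <- random_valid_params(TRUE)
    y <- rnorm(25, mean(params$mu), 0.05)
    swapped <- ms_params(params$p22, params$p11, rev(params$mu), rev(params$sigma))
    expect_equal(hamilton_filter(y, params)$loglik,
                 hamilton_filter(y, swapped)$loglik, tolerance = 1e-10)
  }
})

test_that("stationary distribution solves pi P = pi", {
  expect_equal(stationary_distribution(0.9, 0.9), c(low = 0.5, high = 0.5))
  # closed form p21/(p12+p21) at the table-average probabilities
  sd1 <- stationary_distribution(0.96, 0.9353)
  expect_equal(unname(sd1), c(0.0647 / 0.1047, 0.04 / 0.1047), tolerance = 1e-12)

  set.seed(2)
  for (i in 1:20) {
    p11 <- runif(1); p22 <- runif(1)
    pim <- stationary_distribution(p11, p22)
    expect_equal(sum(pim), 1)
    P <- matrix(c(p11, 1 - p11, 1 - p22, p22), 2, 2, byrow = TRUE)
    expect_equal(as.numeric(pim %*% P), unname(pim), tolerance = 1e-12)
  }
  expect_error(stationary_distribution(1, 1), "reducible")
})

test_that("expected duration is the geometric mean sojourn", {
  expect_equal(expected_duration(0.96), 25)
  expect_equal(round(expected_duration(0.9353), 2), 15.46)
  expect_equal(expected_duration(0), 1)
  expect_error(expected_duration(1), "infinite")
})

test_that("information criteria match the standard definitions", {
  ic <- information_criteria(258.6035, 5, 72)
  expect_equal(ic$aic, -507.207)
  expect_equal(ic$bic, -495.8237, tolerance = 1e-4)
  expect_equal(information_criteria(0, 0, 10), list(aic = 0, bic = 0))
})

test_that("regime classification thresholds smoothed probabilities", {
  probs <- structure(list(smoothed = cbind(low = rep(1, 10), high = rep(0, 10)),
                          start = c(2011, 1)),
                     class = "ms_probs")
  cls <- classify_regimes(probs)
  expect_true(all(cls$labels == "low"))
  expect_equal(nrow(cls$breaks), 0)

  # boundary semantics: exactly 0.5 is "low" at threshold 0.5
  sm <- cbind(low = c(0.9, 0.5, 0.1), high = c(0.1, 0.5, 0.9))
  probs$smoothed <- sm
  at_half <- classify_regimes(probs, threshold = 0.5)
  just_above <- classify_regimes(probs, threshold = 0.5 + 1e-9)
  expect_equal(at_half$labels, c("low", "low", "high"))
  expect_equal(at_half$labels, just_above$labels)
  expect_equal(at_half$breaks$direction, "to_high")
  expect_equal(at_half$breaks$month, "2011-03")
})
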