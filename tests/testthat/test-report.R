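test_that("report ties durations to transition probabilities and formats stars", {
  truth <- ms_preset("refrescos")
  y <- simulate_inflation(sim_config(truth, 240, seed = 2014))
  cpi <- simulate_cpi_from_inflation(y)
  rep <- build_report("refrescos_sim", cpi, starts = 4, seed = 1)

  expect_null(rep$error)
  tab <- rep$table
  p11 <- as.numeric(tab$estimate[tab$quantity == "p11"])
  dur <- as.numeric(tab$estimate[tab$quantity == "duration_low"])
  # duration cell equals 1/(1 - fitted p) up to the 4-dp cell formatting
  expect_equal(dur, round(1 / (1 - rep$fit$params$p11), 4), tolerance = 2e-4)
  expect_equal(p11, round(rep$fit$params$p11, 4))
  # complements printed alongside
  p12 <- as.numeric(tab$estimate[tab$quantity == "p12"])
  expect_equal(p11 + p12, 1, tolerance = 2e-4)
  # strongly separated means should be starred
  expect_match(tab$stars[tab$quantity == "mu_high"], "\\*")
})

test_that("a clean regime step is dated exactly at the simulated switch", {
  # deterministic fixture: 40 low months then 40 high months, tiny noise
  mu <- c(0.02, 0.12)
  s <- rep(c(1L, 2L), each = 40)
  set.seed(99)
  y <- inflation_series(mu[s] + rnorm(80, 0, 0.004), start = c(2010, 1))
  cpi <- simulate_cpi_from_inflation(y)
  rep <- build_report("step", cpi, starts = 4, seed = 1)
  expect_null(rep$error)
  expect_equal(nrow(rep$breaks), 1)
  expect_equal(rep$breaks$index, 41)
  expect_equal(rep$breaks$direction, "to_high")
  expect_equal(rep$breaks$month, month_labels(y)[41])
})

test_that("constant input yields a structured failure, not a crash", {
  cpi <- cpi_series(rep(100, 84))
  rep <- build_report("flat", cpi, starts = 2, seed = 1)
  expect_s3_class(rep, "ms_report")
  expect_match(rep$error, "constant")
  expect_null(rep$fit)
  expect_equal(rep$stats$sd, 0)
  expect_output(print(rep), "FAILED")
})

test_that("fit JSON and probability CSV round-trip the reported numbers", {
  y <- simulate_inflation(sim_config(ms_preset("refrescos"), 200, seed = 2014))
  fit <- ms_fit(y, starts = 4, seed = 1)
  js <- tempfile(fileext = ".json")
  write_fit_json(fit, js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$params$p11, fit$params$p11, tolerance = 1e-12)
  expect_equal(obj$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(obj$durations$low, unname(fit$durations["low"]), tolerance = 1e-12)

  pc <- tempfile(fileext = ".csv")
  write_probs_csv(fit$probs, pc)
  back <- read.csv(pc)
  expect_equal(nrow(back), fit$n_obs)
  expect_equal(back$smoothed, unname(fit$probs$smoothed[, "low"]),
               tolerance = 1e-6)
  expect_equal(back$date[1], month_labels(y)[1])
})

test_that("percent formatting is a pure output-layer concern", {
  expect_equal(fmt_pct(0.0521), "5.21%")
  expect_equal(fmt_pct(0.0521, dec = ","), "5,21%")
  # re-parsing a formatted cell recovers the decimal to formatting precision
  expect_equal(as.numeric(sub("%", "", fmt_pct(0.123456))) / 100, 0.1235,
               tolerance = 1e-12)
})

test_that("cli: simulate then fit end-to-end recovers the preset", {
  sim_csv <- tempfile(fileext = ".csv")
  code <- cli_main(c("simulate", "--preset", "refrescos", "--months", "600",
                     "--seed", "7", "--output", sim_csv))
  expect_equal(code, 0L)
  fit_json <- tempfile(fileext = ".json")
  code <- cli_main(c("fit", "--input", sim_csv, "--starts", "6", "--seed", "1",
                     "--output", fit_json))
  expect_equal(code, 0L)
  obj <- jsonlite::read_json(fit_json, simplifyVector = TRUE)
  expect_lt(abs(obj$params$mu[1] - 0.0326), 0.005)
  expect_lt(abs(obj$params$mu[2] - 0.1494), 0.005)
  expect_lt(abs(obj$params$p11 - 0.9853), 0.03)
})

test_that("cli: transform of a constant index gives an all-zero inflation CSV", {
  cpi_csv <- write_cpi_fixture(rep(100, 24))
  out <- tempfile(fileext = ".csv")
  expect_equal(cli_main(c("transform", "--input", cpi_csv, "--output", out)), 0L)
  infl <- read.csv(out)
  expect_equal(infl$inflation_decimal, rep(0, 12))
})

test_that("cli: usage problems exit 2, and reports are byte-identical", {
  expect_equal(suppressMessages(cli_main(c("report", "--product", "x"))), 2L)
  expect_equal(suppressMessages(cli_main(c("report", "--input",
                                           tempfile(), "--product", "x"))), 2L)
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(cli_main(c("fit", "--input"))), 2L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)

  y <- simulate_inflation(sim_config(ms_preset("pizza"), 120, seed = 3))
  cpi <- simulate_cpi_from_inflation(y)
  cpi_csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(date = month_labels(cpi), value = as.numeric(cpi)),
            cpi_csv, row.names = FALSE, quote = FALSE)
  d1 <- tempfile(); d2 <- tempfile()
  args <- c("report", "--input", cpi_csv, "--product", "pizza_sim",
            "--starts", "4", "--seed", "1")
  expect_equal(cli_main(c(args, "--output-dir", d1)), 0L)
  expect_equal(cli_main(c(args, "--output-dir", d2)), 0L)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
})
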