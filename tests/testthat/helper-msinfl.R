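# shared fixtures: everything is generated in code at test time

# a random but well-posed parameter set; regimes stay identifiable
random_valid_params <- function(switching_variance = FALSE, ar_order = 0L) {
  p11 <- runif(1, 0.7, 0.99)
  p22 <- runif(1, 0.7, 0.99)
  mu <- sort(runif(2, -0.1, 0.2))
  sigma <- if (switching_variance) runif(2, 0.005, 0.05) else runif(1, 0.005, 0.05)
  phi <- if (ar_order > 0L) runif(ar_order, -0.3, 0.3) else numeric(0)
  ms_params(p11, p22, mu, sigma, phi)
}

# write a tidy monthly index CSV and return its path
write_cpi_fixture <- function(values, start = c(2010, 1), path = tempfile(fileext = ".csv"),
                              scramble = FALSE) {
  cpi <- cpi_series(values, start = start)
  df <- data.frame(date = month_labels(cpi), value = as.numeric(cpi))
  if (scramble) df <- df[sample(nrow(df)), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# geometric-growth index: constant annualized inflation `rate`
growth_index <- function(rate, n = 36, base = 100) {
  base * (1 + rate)^(seq_len(n) / 12)
}
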