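#' Simulation configuration
#'
#' Bundles everything a simulation needs: model parameters, horizon, seed,
#' initial-state rule and the base index level used when an index series is
#' derived. One root seed drives two independent sub-streams (regime path
#' and Gaussian noise), so the regime path is invariant to changing only the
#' sigmas — useful for controlled experiments.
#'
#' @param params An [ms_params()] (e.g. from [ms_preset()]).
#' @param n_months Number of months to simulate (>= 1).
#' @param seed Integer root seed.
#' @param init_state `"stationary"` (draw the first regime from the chain's
#'   stationary distribution), `"low"` or `"high"`.
#' @param base_index Index level of the 12 base months when a CPI series is
#'   built from the simulated inflation.
#' @param start Calendar start month `c(year, month)` of the inflation series.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, n_months, seed = 1L,
                       init_state = c("stationary", "low", "high"),
                       base_index = 100, start = c(2011, 1)) {
  init_state <- match.arg(init_state)
  if (!inherits(params, "ms_params")) stop("params must be an ms_params object")
  n_months <- as.integer(n_months)
  if (n_months < 1L) stop("n_months must be >= 1")
  if (base_index <= 0) stop("base_index must be positive")
  structure(list(params = params, n_months = n_months, seed = as.integer(seed),
                 init_state = init_state, base_index = base_index,
                 start = start),
            class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Expects fields `params` (with `p11`, `p22`, `mu`, `sigma`, optional
#' `phi`) or `preset` (a product name), plus the optional `n_months`,
#' `seed`, `init_state`, `base_index`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params <- if (!is.null(cfg$preset)) {
    ms_preset(cfg$preset)
  } else if (!is.null(cfg$params)) {
    with(cfg$params, ms_params(p11, p22, unlist(mu), unlist(sigma),
                               if (is.null(cfg$params$phi)) numeric(0) else unlist(phi)))
  } else stop("config needs either 'preset' or 'params'")
  sim_config(params,
             n_months = if (is.null(cfg$n_months)) 84L else cfg$n_months,
             seed = if (is.null(cfg$seed)) 1L else cfg$seed,
             init_state = if (is.null(cfg$init_state)) "stationary" else cfg$init_state,
             base_index = if (is.null(cfg$base_index)) 100 else cfg$base_index)
}

# two reproducible sub-seeds (path, noise) from the root seed, both < 2^31
sub_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(2^30, 2L)
}

#' Simulate a regime path from the two-state chain
#'
#' Draws the first regime according to `init_state`, then iterates the
#' transition matrix forward. Deterministic given the config's seed.
#'
#' @param config A [sim_config()].
#' @return Integer vector of regimes (1 = low, 2 = high) of length
#'   `n_months`.
#' @export
simulate_regime_path <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  ss <- sub_seeds(config$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(ss[1])
  u <- stats::runif(config$n_months)
  s <- integer(config$n_months)
  s[1] <- switch(config$init_state,
                 stationary = if (u[1] < stationary_distribution(p$p11, p$p22)[["low"]]) 1L else 2L,
                 low = 1L,
                 high = 2L)
  if (config$n_months > 1L) {
    for (t in 2:config$n_months) {
      stay <- if (s[t - 1L] == 1L) p$p11 else p$p22
      s[t] <- if (u[t] < stay) s[t - 1L] else 3L - s[t - 1L]
    }
  }
  s
}

#' Simulate an annualized-inflation series
#'
#' Generates `y_t = mu[s_t] + sigma[s_t] * z_t` with standard-normal noise
#' along a simulated regime path. `sigma = 0` is permitted here (noiseless
#' fixtures), although estimation requires positive sigmas.
#'
#' @param config A [sim_config()].
#' @return An [inflation_series()]; the regime path is attached as attribute
#'   `"regimes"`.
#' @export
simulate_inflation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  s <- simulate_regime_path(config)
  ss <- sub_seeds(config$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(ss[2])
  z <- stats::rnorm(config$n_months)
  sg <- sigma2(p)
  yv <- p$mu[s] + sg[s] * z
  if (any(yv <= -1))
    stop("simulated inflation fell below -1; check the preset's parameters")
  y <- inflation_series(yv, start = config$start)
  attr(y, "regimes") <- s
  y
}

#' Rebuild a consistent CPI index from an inflation series
#'
#' Inverse of [annualized_inflation()]: the first 12 index months are set to
#' `base_index`, and from month 13 on `p_t = p_{t-12} * (1 + pi_t)`.
#' Feeding the result back through [annualized_inflation()] reproduces the
#' input exactly.
#'
#' @param inflation An [inflation_series()] (all values > -1).
#' @param base_index Positive level of the 12 base months.
#' @return A [cpi_series()] 12 months longer than the input, starting one
#'   year earlier.
#' @export
simulate_cpi_from_inflation <- function(inflation, base_index = 100) {
  pi_t <- as.numeric(inflation)
  if (any(pi_t <= -1)) stop("inflation values must be > -1")
  if (base_index <= 0) stop("base_index must be positive")
  n <- length(pi_t)
  p <- numeric(n + 12L)
  p[1:12] <- base_index
  for (t in seq_len(n)) p[t + 12L] <- p[t] * (1 + pi_t[t])
  start <- if (inherits(inflation, "ts")) {
    key <- stats::start(inflation)[1] * 12L + stats::start(inflation)[2] - 1L - 12L
    c(key %/% 12L, key %% 12L + 1L)
  } else c(2010, 1)
  cpi_series(p, start = start)
}

preset_rows <- function() {
  # point estimates of the published two-state fits, one row per product;
  # sigma_high is NA where a single (shared) sigma was estimated
  tab <- rbind(
    data.frame(product = "azucar",               label = "Azucar",                taxed = FALSE, table = 2,
               mu_low = -0.2009, mu_high = 0.1446, sigma_low = 0.0973, sigma_high = NA,
               p11 = 0.9471, p22 = 0.9639, loglik = 55.7190, aic = -101.438,  bic = -90.0547),
    data.frame(product = "refrescos",            label = "Refrescos",             taxed = TRUE,  table = 2,
               mu_low = 0.0326, mu_high = 0.1494, sigma_low = 0.0059, sigma_high = NA,
               p11 = 0.9853, p22 = 0.9064, loglik = 258.6035, aic = -507.2069, bic = -495.8236),
    data.frame(product = "bebidas_concentradas", label = "Bebidas concentradas",  taxed = TRUE,  table = 2,
               mu_low = 0.0023, mu_high = 0.0596, sigma_low = 0.0201, sigma_high = NA,
               p11 = 0.9552, p22 = 0.9197, loglik = 167.4424, aic = -324.8847, bic = -313.5014),
    data.frame(product = "pan_dulce",            label = "Pan dulce",             taxed = TRUE,  table = 2,
               mu_low = 0.0107, mu_high = 0.0931, sigma_low = 0.0274, sigma_high = 0.0174,
               p11 = 0.9495, p22 = 0.9627, loglik = 164.5797, aic = -317.1594, bic = -303.4994),
    data.frame(product = "panecillos",           label = "Panecillos",            taxed = TRUE,  table = 2,
               mu_low = 0.0495, mu_high = 0.1315, sigma_low = 0.0224, sigma_high = NA,
               p11 = 0.9852, p22 = 0.9063, loglik = 162.9166, aic = -315.8333, bic = -304.4499),
    data.frame(product = "pasteles",             label = "Pasteles",              taxed = TRUE,  table = 2,
               mu_low = 0.0322, mu_high = 0.0822, sigma_low = 0.0189, sigma_high = 0.0108,
               p11 = 0.9583, p22 = 0.9244, loglik = 188.2442, aic = -364.4885, bic = -350.8285),
    data.frame(product = "galletas",             label = "Galletas",              taxed = TRUE,  table = 2,
               mu_low = 0.0368, mu_high = 0.0816, sigma_low = 0.0125, sigma_high = NA,
               p11 = 0.9852, p22 = 0.9061, loglik = 204.9204, aic = -399.8407, bic = -388.4574),
    data.frame(product = "manteca",              label = "Manteca",               taxed = FALSE, table = 2,
               mu_low = 0.0082, mu_high = 0.1003, sigma_low = 0.0282, sigma_high = NA,
               p11 = 0.9627, p22 = 0.9043, loglik = 142.3791, aic = -274.7582, bic = -263.3749),
    data.frame(product = "chorizo",              label = "Chorizo",               taxed = FALSE, table = 2,
               mu_low = 0.0399, mu_high = 0.0904, sigma_low = 0.0130, sigma_high = NA,
               p11 = 0.9629, p22 = 0.9072, loglik = 197.4731, aic = -384.9463, bic = -373.5629),
    data.frame(product = "tocino",               label = "Tocino",                taxed = FALSE, table = 2,
               mu_low = 0.0543, mu_high = 0.1061, sigma_low = 0.0217, sigma_high = NA,
               p11 = 0.9314, p22 = 0.9152, loglik = 161.4526, aic = -312.9052, bic = -301.5219),
    data.frame(product = "manteca_vegetal",      label = "Manteca vegetal",       taxed = FALSE, table = 3,
               mu_low = -0.0246, mu_high = 0.0734, sigma_low = 0.0170, sigma_high = 0.0452,
               p11 = 0.9610, p22 = 0.9816, loglik = 146.80, aic = -281.60, bic = -267.94),
    data.frame(product = "leche_condensada",     label = "Leche condensada",      taxed = TRUE,  table = 3,
               mu_low = 0.0019, mu_high = 0.0504, sigma_low = 0.0191, sigma_high = NA,
               p11 = 0.9562, p22 = 0.9816, loglik = 176.80, aic = -343.59, bic = -332.21),
    data.frame(product = "helados",              label = "Helados",               taxed = TRUE,  table = 3,
               mu_low = 0.0312, mu_high = 0.0799, sigma_low = 0.0148, sigma_high = NA,
               p11 = 0.9686, p22 = 0.9158, loglik = 190.50, aic = -370.99, bic = -359.62),
    data.frame(product = "mayonesa",             label = "Mayonesa",              taxed = FALSE, table = 3,
               mu_low = 0.0180, mu_high = 0.0682, sigma_low = 0.0184, sigma_high = NA,
               p11 = 0.9612, p22 = 0.9503, loglik = 175.90, aic = -341.80, bic = -330.42),
    data.frame(product = "frituras",             label = "Frituras",              taxed = TRUE,  table = 3,
               mu_low = 0.0319, mu_high = 0.0834, sigma_low = 0.0181, sigma_high = NA,
               p11 = 0.9599, p22 = 0.9133, loglik = 174.62, aic = -339.24, bic = -327.85),
    data.frame(product = "dulces",               label = "Dulces",                taxed = TRUE,  table = 3,
               mu_low = 0.0216, mu_high = 0.0896, sigma_low = 0.0152, sigma_high = 0.0239,
               p11 = 0.9870, p22 = 0.9841, loglik = 181.30, aic = -350.60, bic = -336.940),
    data.frame(product = "cajetas_mermeladas",   label = "Cajetas y mermeladas",  taxed = TRUE,  table = 3,
               mu_low = 0.0332, mu_high = 0.0738, sigma_low = 0.0120, sigma_high = NA,
               p11 = 0.9465, p22 = 0.8801, loglik = 201.28, aic = -392.55, bic = -381.17),
    data.frame(product = "gelatina",             label = "Gelatina",              taxed = TRUE,  table = 3,
               mu_low = -0.0011, mu_high = 0.0386, sigma_low = 0.0010, sigma_high = 0.0192,
               p11 = 0.8899, p22 = 0.9631, loglik = 184.32, aic = -356.64, bic = -342.98),
    data.frame(product = "pizza",                label = "Pizza",                 taxed = FALSE, table = 3,
               mu_low = 0.0196, mu_high = 0.0473, sigma_low = 0.0097, sigma_high = NA,
               p11 = 0.9868, p22 = 0.9839, loglik = 226.05, aic = -442.09, bic = -430.71)
  )
  tab$switching_variance <- !is.na(tab$sigma_high)
  tab
}

#' Published point estimates for the 19 food and beverage products
#'
#' The two-state switching-model estimates for each monthly INPC product
#' series (regime means, sigma(s), self-transition probabilities) together
#' with the reported log-likelihood, AIC and BIC, stored exactly as printed
#' (decimal fractions; no back-solving of rounding). These drive the
#' simulation presets and the arithmetic-identity checks.
#'
#' @return A data frame with one row per product; columns `product`,
#'   `label`, `taxed`, `table`, `mu_low`, `mu_high`, `sigma_low`,
#'   `sigma_high` (`NA` when a single sigma was estimated),
#'   `switching_variance`, `p11`, `p22`, `loglik`, `aic`, `bic`.
#' @export
#' @examples
#' head(ms_presets())
ms_presets <- function() preset_rows()

#' Model parameters for a named product preset
#'
#' @param name Product identifier, one of `ms_presets()$product` (e.g.
#'   `"refrescos"`, `"pan_dulce"`, `"gelatina"`).
#' @return An [ms_params()] with the printed point estimates; `sigma` has
#'   length 2 for the five switching-variance products.
#' @export
#' @examples
#' ms_preset("refrescos")
ms_preset <- function(name) {
  tab <- preset_rows()
  i <- match(name, tab$product)
  if (is.na(i)) {
    stop("unknown preset '", name, "'; valid names: ",
         paste(tab$product, collapse = ", "))
  }
  sg <- if (tab$switching_variance[i]) c(tab$sigma_low[i], tab$sigma_high[i]) else tab$sigma_low[i]
  ms_params(p11 = tab$p11[i], p22 = tab$p22[i],
            mu = c(tab$mu_low[i], tab$mu_high[i]), sigma = sg)
}
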