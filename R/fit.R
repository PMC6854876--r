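# Optimization runs in an unconstrained space: logit for the two
# self-transition probabilities, log for the sigmas (with a 1e-6 floor so a
# point mass cannot collapse the likelihood), identity for means and AR
# coefficients. This keeps every iterate interior and makes the Hessian in
# the transformed space usable for standard errors.

SIGMA_FLOOR <- 1e-6

params_to_eta <- function(params, spec) {
  c(stats::qlogis(params$p11), stats::qlogis(params$p22), params$mu,
    log(pmax(sigma2(params)[seq_len(if (spec$switching_variance) 2L else 1L)] -
               SIGMA_FLOOR, 1e-12)),
    params$phi)
}

eta_to_params <- function(eta, spec) {
  ns <- if (spec$switching_variance) 2L else 1L
  sg <- SIGMA_FLOOR + exp(eta[5:(4 + ns)])
  phi <- if (spec$ar_order > 0L) eta[(5 + ns):(4 + ns + spec$ar_order)] else numeric(0)
  ms_params(p11 = stats::plogis(eta[1]), p22 = stats::plogis(eta[2]),
            mu = eta[3:4], sigma = sg, phi = phi)
}

eta_names <- function(spec) {
  c("p11", "p22", "mu_low", "mu_high",
    if (spec$switching_variance) c("sigma_low", "sigma_high") else "sigma",
    if (spec$ar_order > 0L) paste0("phi_", seq_len(spec$ar_order)))
}

ms_negll <- function(eta, yv, spec) {
  p <- tryCatch(eta_to_params(eta, spec), error = function(e) NULL)
  if (is.null(p)) return(1e10)
  v <- tryCatch(ms_filter_cpp(yv, p$p11, p$p22, p$mu, sigma2(p), p$phi)$loglik,
                error = function(e) NA_real_)
  if (!is.finite(v)) return(1e10)
  -v
}

# multi-start grid: regime means at data quantiles, sticky transition
# probabilities, seeded jitter beyond the 4 base combinations
ms_starts <- function(yv, spec, starts, seed) {
  qs <- stats::quantile(yv, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  base_mu <- list(c(qs[2], qs[3]), c(qs[1], qs[4]))
  base_p <- c(0.9, 0.95)
  s0 <- max(stats::sd(yv) / 2, 10 * SIGMA_FLOOR)
  grid <- expand.grid(mu = 1:2, p = 1:2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  lapply(seq_len(starts), function(i) {
    g <- grid[(i - 1L) %% nrow(grid) + 1L, ]
    mu <- base_mu[[g$mu]]
    pstay <- rep(base_p[g$p], 2)
    sg <- rep(s0, if (spec$switching_variance) 2L else 1L)
    eta <- c(stats::qlogis(pstay), mu, log(sg), rep(0, spec$ar_order))
    if (i > nrow(grid)) {
      eta <- eta + stats::rnorm(length(eta),
                                sd = c(0.5, 0.5, rep(stats::sd(yv) / 5, 2),
                                       rep(0.3, length(sg)),
                                       rep(0.1, spec$ar_order)))
    }
    eta
  })
}

canonicalize <- function(params, spec) {
  if (params$mu[1] <= params$mu[2]) return(params)
  sg <- params$sigma
  if (length(sg) == 2L) sg <- rev(sg)
  ms_params(p11 = params$p22, p22 = params$p11, mu = rev(params$mu),
            sigma = sg, phi = params$phi)
}

#' Fit a two-state Markov-switching model by maximum likelihood
#'
#' Maximizes the Hamilton-filter log-likelihood over a multi-start BFGS
#' search in transformed (logit/log) parameter space, canonically orders the
#' states so regime 1 is the low-inflation regime, and assembles the full
#' fit: estimates, standard errors, smoothed regime probabilities, expected
#' regime durations and information criteria.
#'
#' @param y An [inflation_series()] (or numeric vector).
#' @param spec An [ms_spec()]; default is the mean-only shared-variance model.
#' @param starts Number of optimization starts (default 8).
#' @param seed Integer seed for the start-point jitter (estimation itself is
#'   deterministic given the starts).
#' @param se_kind `"robust"` (sandwich, default), `"hessian"`, or `"none"`.
#' @return An object of class `ms_fit`: a list with `spec`, `params`, `se`
#'   (named, natural scale, including durations), `loglik`, `aic`, `bic`,
#'   `n_obs`, `n_params`, `probs` (predicted/filtered/smoothed), `durations`,
#'   `converged`, `warnings` and per-start diagnostics (`start_loglik`).
#' @export
#' @examples
#' y <- simulate_inflation(sim_config(ms_preset("refrescos"),
#'                                    n_months = 120, seed = 1))
#' fit <- ms_fit(y, starts = 4, seed = 1, se_kind = "none")
#' fit$params
ms_fit <- function(y, spec = ms_spec(), starts = 8L, seed = 1L,
                   se_kind = c("robust", "hessian", "none")) {
  se_kind <- match.arg(se_kind)
  yv <- as.numeric(y)
  if (length(yv) - spec$ar_order < n_free_params(spec) + 2L)
    stop("series too short to fit ", n_free_params(spec), " parameters")
  if (stats::sd(yv) == 0)
    stop("constant series: regime means and variances are unidentified")
  if (starts < 1L) stop("starts must be >= 1")
  eta0 <- ms_starts(yv, spec, starts, seed)
  runs <- lapply(eta0, function(e0) {
    tryCatch(stats::optim(e0, ms_negll, yv = yv, spec = spec, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-12)),
             error = function(err) list(value = Inf, convergence = 99L,
                                        message = conditionMessage(err)))
  })
  vals <- vapply(runs, function(r) r$value, 0)
  codes <- vapply(runs, function(r) r$convergence, 0L)
  ok <- codes == 0L & is.finite(vals)
  if (!any(ok)) {
    stop("no optimization start converged; convergence codes: ",
         paste(codes, collapse = ", "), "; objective values: ",
         paste(signif(vals, 6), collapse = ", "))
  }
  best <- which(ok)[which.min(vals[ok])]
  eta_hat <- runs[[best]]$par
  params <- canonicalize(eta_to_params(eta_hat, spec), spec)
  loglik <- -vals[best]

  warnings_out <- character(0)
  if (any(sigma2(params) < 10 * SIGMA_FLOOR))
    warnings_out <- c(warnings_out,
                      "a regime standard deviation is at its lower bound (possible point-mass collapse)")

  fl <- hamilton_filter(if (inherits(y, "ts")) y else yv, params, spec)
  probs <- kim_smoother(fl$probs, params)
  n_obs <- length(yv) - spec$ar_order
  k <- n_free_params(spec)
  ic <- information_criteria(loglik, k, n_obs)
  durations <- c(low = expected_duration(params$p11),
                 high = expected_duration(params$p22))

  se <- NULL
  if (se_kind != "none") {
    se <- tryCatch(standard_errors(yv, params, spec, kind = se_kind),
                   error = function(e) {
                     warnings_out <<- c(warnings_out,
                                        paste("standard errors unavailable:",
                                              conditionMessage(e)))
                     NULL
                   })
  }

  structure(list(spec = spec, params = params, se = se,
                 loglik = loglik, aic = ic$aic, bic = ic$bic,
                 n_obs = n_obs, n_params = k, probs = probs,
                 durations = durations,
                 converged = TRUE, warnings = warnings_out,
                 start_loglik = -vals, start_codes = codes,
                 se_kind = if (is.null(se)) "none" else se_kind),
            class = "ms_fit")
}

#' Standard errors of switching-model estimates
#'
#' Computes standard errors at a (local) maximum of the likelihood.
#' `kind = "hessian"` inverts the negative numerical Hessian of the
#' log-likelihood; `kind = "robust"` (the default reported in the estimate
#' tables) is the sandwich `H^-1 S'S H^-1` combining the Hessian with the
#' outer product of per-observation scores. Both are computed in the
#' transformed (logit/log) space where the optimum is interior, then mapped
#' to the natural scale — including the expected durations — by the delta
#' method.
#'
#' @inheritParams ms_fit
#' @param params Fitted [ms_params()] (an interior optimum).
#' @param kind `"robust"` or `"hessian"`.
#' @return Named numeric vector of standard errors for `p11`, `p22`,
#'   `mu_low`, `mu_high`, the sigma(s), any `phi`, and `duration_low`,
#'   `duration_high`. The transformed-space covariance is attached as
#'   attribute `"cov_eta"`.
#' @export
standard_errors <- function(y, params, spec = NULL,
                            kind = c("robust", "hessian")) {
  kind <- match.arg(kind)
  spec <- params_spec(params, spec)
  yv <- as.numeric(y)
  eta <- params_to_eta(params, spec)
  negll <- function(e) ms_negll(e, yv, spec)
  H <- pracma::hessian(negll, eta)
  if (any(!is.finite(H)) || rcond(H) < 1e-10)
    stop("singular Hessian (regimes may be unidentified); ",
         "consider a ridge penalty or re-fitting from other starts")
  bread <- solve(H)
  if (kind == "robust") {
    condll <- function(e) {
      p <- eta_to_params(e, spec)
      as.numeric(ms_filter_cpp(yv, p$p11, p$p22, p$mu, sigma2(p), p$phi)$condloglik)
    }
    S <- pracma::jacobian(condll, eta)
    V <- bread %*% (t(S) %*% S) %*% bread
  } else {
    V <- bread
  }
  g <- function(e) {
    p <- eta_to_params(e, spec)
    c(p$p11, p$p22, p$mu, p$sigma, p$phi,
      expected_duration(p$p11), expected_duration(p$p22))
  }
  J <- pracma::jacobian(g, eta)
  se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  names(se) <- c(eta_names(spec), "duration_low", "duration_high")
  attr(se, "cov_eta") <- V
  se
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("<ms_fit> 2-state Gaussian switching model, %s variance, AR(%d)\n",
              if (x$spec$switching_variance) "switching" else "shared",
              x$spec$ar_order))
  est <- c(x$params$p11, x$params$p22, x$params$mu, x$params$sigma, x$params$phi)
  nm <- eta_names(x$spec)
  tab <- data.frame(estimate = sprintf("%.4f", est))
  rownames(tab) <- nm
  if (!is.null(x$se)) tab$se <- sprintf("(%.4f)", x$se[nm])
  print(tab)
  cat(sprintf("durations: low %.2f months, high %.2f months\n",
              x$durations["low"], x$durations["high"]))
  cat(sprintf("loglik %.4f | AIC %.4f | BIC %.4f | n = %d, k = %d\n",
              x$loglik, x$aic, x$bic, x$n_obs, x$n_params))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
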