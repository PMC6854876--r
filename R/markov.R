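#' Model structure of a two-state switching model
#'
#' Fixes the structural choices of the regime-switching model: the number of
#' latent states (always 2: a low-inflation and a high-inflation regime),
#' whether the residual standard deviation switches with the regime, and the
#' order of a non-switching autoregressive component.
#'
#' @param switching_variance Logical; if `TRUE` each regime has its own
#'   residual standard deviation, otherwise one sigma is shared.
#' @param ar_order Non-negative integer; order of the (non-switching)
#'   autoregression on mean-adjusted lags. The default model is mean-only
#'   (`ar_order = 0`).
#' @return An object of class `ms_spec`.
#' @export
ms_spec <- function(switching_variance = FALSE, ar_order = 0L) {
  ar_order <- as.integer(ar_order)
  if (ar_order < 0L) stop("ar_order must be >= 0")
  structure(list(n_states = 2L,
                 switching_variance = isTRUE(switching_variance),
                 ar_order = ar_order),
            class = "ms_spec")
}

#' Parameters of a two-state switching model
#'
#' Bundles the transition probabilities, regime means, regime standard
#' deviations and optional AR coefficients. Regime 1 is the low-inflation
#' state by the package's canonical ordering (`mu[1] < mu[2]` after fitting);
#' the constructor does not reorder, so simulation presets keep their printed
#' orientation.
#'
#' @param p11,p22 Self-transition probabilities of the low and high regime,
#'   in `[0, 1]` (estimation keeps them interior; the boundary is allowed so
#'   absorbing chains can be simulated).
#' @param mu Length-2 numeric: regime means (decimal inflation).
#' @param sigma Length-1 (shared) or length-2 (switching) standard
#'   deviations; must be non-negative (zero only meaningful in simulation).
#' @param phi Numeric vector of AR coefficients (possibly empty).
#' @return An object of class `ms_params`.
#' @export
ms_params <- function(p11, p22, mu, sigma, phi = numeric(0)) {
  if (!(is.numeric(p11) && length(p11) == 1 && p11 >= 0 && p11 <= 1))
    stop("p11 must be a probability in [0, 1]")
  if (!(is.numeric(p22) && length(p22) == 1 && p22 >= 0 && p22 <= 1))
    stop("p22 must be a probability in [0, 1]")
  if (length(mu) != 2 || anyNA(mu)) stop("mu must be two regime means")
  if (!length(sigma) %in% 1:2 || anyNA(sigma) || any(sigma < 0))
    stop("sigma must be 1 (shared) or 2 (switching) non-negative values")
  structure(list(p11 = as.numeric(p11), p22 = as.numeric(p22),
                 mu = as.numeric(mu), sigma = as.numeric(sigma),
                 phi = as.numeric(phi)),
            class = "ms_params")
}

# sigma always length 2 for the filter; spec inferred from params when absent
params_spec <- function(params, spec = NULL) {
  if (is.null(spec)) {
    spec <- ms_spec(switching_variance = length(params$sigma) == 2L,
                    ar_order = length(params$phi))
  } else {
    if (spec$ar_order != length(params$phi))
      stop("spec ar_order does not match length of phi")
    if (spec$switching_variance && length(params$sigma) == 1L)
      stop("spec asks for switching variance but a single sigma was given")
  }
  spec
}

sigma2 <- function(params) {
  if (length(params$sigma) == 2L) params$sigma else rep(params$sigma, 2L)
}

#' Number of free parameters of a model structure
#'
#' Two transition probabilities, two regime means, one or two standard
#' deviations, plus the AR coefficients: 5 for the shared-variance mean-only
#' model, 6 with switching variance.
#'
#' @param spec An [ms_spec()].
#' @return Integer count of free parameters.
#' @export
n_free_params <- function(spec) {
  2L + 2L + (if (spec$switching_variance) 2L else 1L) + spec$ar_order
}

#' Stationary distribution of a two-state chain
#'
#' Solves `pi P = pi` for the 2x2 transition matrix with rows
#' `(p11, 1-p11)` and `(1-p22, p22)`: the result is
#' `(p21, p12) / (p12 + p21)`.
#'
#' @param p11,p22 Self-transition probabilities in `[0, 1]`, not both 1.
#' @return Named numeric vector `c(low = , high = )` summing to 1.
#' @export
#' @examples
#' stationary_distribution(0.96, 0.9353)
stationary_distribution <- function(p11, p22) {
  if (any(c(p11, p22) < 0) || any(c(p11, p22) > 1))
    stop("p11 and p22 must lie in [0, 1]")
  p12 <- 1 - p11
  p21 <- 1 - p22
  if (p12 + p21 == 0)
    stop("reducible chain: p11 = p22 = 1 has no unique stationary distribution")
  c(low = p21 / (p12 + p21), high = p12 / (p12 + p21))
}

#' Expected regime duration (persistence)
#'
#' The mean sojourn time of a regime with self-transition probability
#' `p_stay` is `1 / (1 - p_stay)` months: a regime kept with probability
#' 0.96 each month lasts 25 months on average.
#'
#' @param p_stay Self-transition probability in `[0, 1)`.
#' @return Expected duration in months.
#' @export
#' @examples
#' expected_duration(0.96)    # 25 months
#' expected_duration(0.9353)  # 15.46 months
expected_duration <- function(p_stay) {
  if (any(p_stay < 0) || any(p_stay >= 1))
    stop("p_stay must lie in [0, 1); p_stay = 1 means an infinite sojourn")
  1 / (1 - p_stay)
}

#' Akaike and Schwarz information criteria
#'
#' `AIC = -2 loglik + 2 k` and `BIC = -2 loglik + k log(n)`, the criteria
#' used to choose the AR order and variance structure.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters `k`.
#' @param n_obs Number of likelihood observations `n`.
#' @return Named list with elements `aic` and `bic`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (n_params < 0) stop("n_params must be >= 0")
  if (n_obs < 1) stop("n_obs must be >= 1")
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + n_params * log(n_obs))
}

probs_start <- function(y, ar_order) {
  ym <- month_index(y)[ar_order + 1L, ]
  c(ym[["year"]], ym[["month"]])
}

#' Hamilton filter: likelihood and one-step regime probabilities
#'
#' Runs the forward recursion of the two-state Gaussian switching model over
#' an inflation series: at each month it combines the predicted regime
#' distribution with the Gaussian emission density, yielding the exact log
#' marginal likelihood (initial state drawn from the stationary distribution
#' of the transition matrix) together with predicted and filtered regime
#' probabilities. With `ar_order > 0` the recursion runs on the expanded
#' joint state of the current and lagged regimes, and the first `ar_order`
#' observations condition the likelihood as regressors.
#'
#' @param y An [inflation_series()] (or numeric vector).
#' @param params An [ms_params()].
#' @param spec Optional [ms_spec()]; inferred from `params` if omitted.
#' @return A list with `loglik`, `condloglik` (per-month log conditional
#'   densities) and `probs`, an `ms_probs` object holding `predicted` and
#'   `filtered` regime-probability matrices (columns low/high).
#' @export
hamilton_filter <- function(y, params, spec = NULL) {
  spec <- params_spec(params, spec)
  yv <- as.numeric(y)
  out <- ms_filter_cpp(yv, params$p11, params$p22, params$mu, sigma2(params),
                       params$phi)
  start <- if (inherits(y, "ts")) probs_start(y, spec$ar_order) else NULL
  probs <- structure(list(predicted = out$predicted, filtered = out$filtered,
                          smoothed = NULL,
                          pred_joint = out$pred_joint,
                          filt_joint = out$filt_joint,
                          ar_order = spec$ar_order, start = start),
                     class = "ms_probs")
  colnames(probs$predicted) <- colnames(probs$filtered) <- c("low", "high")
  list(loglik = out$loglik, condloglik = as.numeric(out$condloglik),
       probs = probs)
}

# transition matrix over the joint state space used by the filter
joint_transition <- function(params, ar_order) {
  M <- 2L^(ar_order + 1L)
  P <- matrix(c(params$p11, 1 - params$p11, 1 - params$p22, params$p22),
              2, 2, byrow = TRUE)
  A <- matrix(0, M, M)
  mask <- bitwShiftL(1L, ar_order) - 1L
  for (m in 0:(M - 1L)) {
    s0 <- bitwAnd(m, 1L)
    shifted <- bitwShiftL(bitwAnd(m, mask), 1L)
    A[m + 1L, shifted + 1L] <- P[s0 + 1L, 1L]
    A[m + 1L, bitwOr(shifted, 1L) + 1L] <- P[s0 + 1L, 2L]
  }
  A
}

#' Kim smoother: full-sample regime probabilities
#'
#' Backward pass over the filter output producing smoothed probabilities
#' `P(s_t | y_1..T)` — the quantities plotted as the "probability of the
#' low-inflation regime". The last month's smoothed probabilities equal the
#' filtered ones by construction.
#'
#' @param probs An `ms_probs` object from [hamilton_filter()].
#' @param params The [ms_params()] used by the filter.
#' @return The `ms_probs` object with a `smoothed` matrix added.
#' @export
kim_smoother <- function(probs, params) {
  if (!inherits(probs, "ms_probs")) stop("probs must come from hamilton_filter()")
  A <- joint_transition(params, probs$ar_order)
  fj <- probs$filt_joint
  pj <- probs$pred_joint
  Teff <- nrow(fj)
  sj <- fj
  if (Teff > 1L) {
    for (t in (Teff - 1L):1L) {
      ratio <- sj[t + 1L, ] / pj[t + 1L, ]
      ratio[pj[t + 1L, ] == 0] <- 0
      sj[t, ] <- fj[t, ] * as.numeric(A %*% ratio)
    }
  }
  low_states <- bitwAnd(seq_len(ncol(sj)) - 1L, 1L) == 0L
  smoothed <- cbind(low = rowSums(sj[, low_states, drop = FALSE]),
                    high = rowSums(sj[, !low_states, drop = FALSE]))
  probs$smoothed <- smoothed
  probs$smooth_joint <- sj
  probs
}

#' Brute-force log-likelihood by regime-path enumeration
#'
#' Independent oracle for [hamilton_filter()]: sums the path prior
#' (stationary initial state times transition probabilities) multiplied by
#' the Gaussian emission likelihood over all `2^T` regime paths. Only
#' feasible for short series (`T <= 14`).
#'
#' @inheritParams hamilton_filter
#' @return The log marginal likelihood.
#' @export
brute_force_loglik <- function(y, params, spec = NULL) {
  brute_force_paths(y, params, spec)$loglik
}

#' Brute-force smoothed regime marginals
#'
#' Posterior regime probabilities `P(s_t | y)` obtained by explicit path
#' enumeration; the oracle against which [kim_smoother()] is validated.
#'
#' @inheritParams hamilton_filter
#' @return Matrix `T x 2` (columns low/high) of posterior regime marginals.
#' @export
brute_force_posterior <- function(y, params, spec = NULL) {
  bf <- brute_force_paths(y, params, spec)
  w <- exp(bf$logw - max(bf$logw))
  w <- w / sum(w)
  marg <- cbind(low = colSums(w * (bf$paths == 1L)),
                high = colSums(w * (bf$paths == 2L)))
  marg
}

brute_force_paths <- function(y, params, spec = NULL) {
  spec <- params_spec(params, spec)
  yv <- as.numeric(y)
  Tn <- length(yv)
  p <- spec$ar_order
  if (Tn > 14L) stop("path enumeration limited to T <= 14, got T = ", Tn)
  if (Tn <= p) stop("series too short for AR order")
  sg <- sigma2(params)
  if (any(sg <= 0)) stop("regime standard deviations must be strictly positive")
  pim <- stationary_distribution(params$p11, params$p22)
  P <- matrix(c(params$p11, 1 - params$p11, 1 - params$p22, params$p22),
              2, 2, byrow = TRUE)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))  # 2^T x T, regimes 1/2
  colnames(paths) <- NULL
  logw <- log(pim)[paths[, 1L]]
  if (Tn > 1L) {
    for (t in 2:Tn) logw <- logw + log(P[cbind(paths[, t - 1L], paths[, t])])
  }
  for (t in (p + 1L):Tn) {
    mean_t <- params$mu[paths[, t]]
    if (p > 0L) {
      for (i in seq_len(p))
        mean_t <- mean_t + params$phi[i] * (yv[t - i] - params$mu[paths[, t - i]])
    }
    logw <- logw + stats::dnorm(yv[t], mean_t, sg[paths[, t]], log = TRUE)
  }
  m <- max(logw)
  list(loglik = m + log(sum(exp(logw - m))), logw = logw, paths = paths)
}

#' Label months by regime and locate regime breaks
#'
#' Thresholds the smoothed probability of the high-inflation regime: months
#' with `P(s = high | y) > threshold` are labelled `"high"`, the rest
#' `"low"`. A break is any month whose label differs from the previous
#' month's; its direction records whether inflation moved into the high or
#' the low regime.
#'
#' @param probs An `ms_probs` object with smoothed probabilities (run
#'   [kim_smoother()] first).
#' @param threshold Probability cut-off, default 0.5.
#' @return A list with `labels` (character vector, one per month) and
#'   `breaks` (data frame with `index`, `month` label when dates are known,
#'   and `direction`, `"to_high"` or `"to_low"`).
#' @export
classify_regimes <- function(probs, threshold = 0.5) {
  if (is.null(probs$smoothed))
    stop("smoothed probabilities missing; run kim_smoother() first")
  high <- probs$smoothed[, "high"] > threshold
  labels <- ifelse(high, "high", "low")
  chg <- which(labels[-1L] != labels[-length(labels)]) + 1L
  months <- if (!is.null(probs$start)) {
    key0 <- probs$start[1] * 12L + probs$start[2] - 1L
    keys <- key0 + seq_along(labels) - 1L
    sprintf("%04d-%02d", keys %/% 12L, keys %% 12L + 1L)
  } else as.character(seq_along(labels))
  breaks <- data.frame(index = chg,
                       month = months[chg],
                       direction = ifelse(labels[chg] == "high",
                                          "to_high", "to_low"),
                       stringsAsFactors = FALSE)
  list(labels = labels, months = months, breaks = breaks)
}

#' @export
print.ms_params <- function(x, ...) {
  sg <- x$sigma
  cat("<ms_params>\n")
  cat(sprintf("  mu    (low, high): %.4f, %.4f\n", x$mu[1], x$mu[2]))
  cat(sprintf("  sigma %s: %s\n",
              if (length(sg) == 2) "(low, high)" else "(shared)",
              paste(sprintf("%.4f", sg), collapse = ", ")))
  cat(sprintf("  p11 = %.4f (stay low), p22 = %.4f (stay high)\n", x$p11, x$p22))
  if (length(x$phi)) cat("  phi:", paste(sprintf("%.4f", x$phi), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ms_spec <- function(x, ...) {
  cat(sprintf("<ms_spec> 2 states, %s variance, AR(%d)\n",
              if (x$switching_variance) "switching" else "shared", x$ar_order))
  invisible(x)
}
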