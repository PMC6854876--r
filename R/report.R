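fmt_num <- function(x, digits = 4, dec = ".") {
  s <- sprintf(paste0("%.", digits, "f"), x)
  if (dec != ".") s <- gsub(".", dec, s, fixed = TRUE)
  s
}

#' Format a decimal fraction as a percentage
#'
#' Two decimals, percent only at the reporting layer; internal values stay
#' decimal fractions throughout the pipeline.
#'
#' @param x Numeric decimal fraction(s).
#' @param dec Decimal mark; `","` gives the locale used in the published
#'   tables.
#' @return Character vector like `"5.21%"`.
#' @export
fmt_pct <- function(x, dec = ".") paste0(fmt_num(100 * x, 2, dec), "%")

stars_for <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Estimate table of a fitted switching model
#'
#' Lays the fit out like a published estimates column: regime means,
#' sigma(s), transition probabilities, expected durations and decision
#' criteria, with robust standard errors in a companion column and
#' two-sided z-test significance stars (* P < 0.1, ** P < 0.05,
#' *** P < 0.01).
#'
#' @param fit An `ms_fit`.
#' @param dec Decimal mark for formatting (`","` opts into the
#'   decimal-comma locale).
#' @return A data frame with columns `quantity`, `estimate`, `se`, `stars`.
#' @export
format_estimates <- function(fit, dec = ".") {
  p <- fit$params
  sw <- fit$spec$switching_variance
  est <- c(mu_low = p$mu[1], mu_high = p$mu[2],
           if (sw) c(sigma_low = p$sigma[1], sigma_high = p$sigma[2])
           else c(sigma = p$sigma),
           p11 = p$p11, p12 = 1 - p$p11, p21 = 1 - p$p22, p22 = p$p22,
           duration_low = unname(fit$durations["low"]),
           duration_high = unname(fit$durations["high"]),
           loglik = fit$loglik, aic = fit$aic, bic = fit$bic)
  if (fit$spec$ar_order > 0)
    est <- c(est, stats::setNames(p$phi, paste0("phi_", seq_along(p$phi))))
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (!is.null(fit$se)) {
    have <- intersect(names(fit$se), names(se))
    se[have] <- fit$se[have]
    # complements share the SE of their probability
    if (is.na(se["p12"])) se["p12"] <- fit$se["p11"]
    if (is.na(se["p21"])) se["p21"] <- fit$se["p22"]
  }
  z <- abs(est) / se
  pval <- 2 * stats::pnorm(-z)
  starred <- c("mu_low", "mu_high",
               if (sw) c("sigma_low", "sigma_high") else "sigma")
  data.frame(
    quantity = names(est),
    estimate = fmt_num(est, 4, dec),
    se = ifelse(is.na(se), "", paste0("(", fmt_num(se, 4, dec), ")")),
    stars = ifelse(names(est) %in% starred & !is.na(pval), stars_for(pval), ""),
    stringsAsFactors = FALSE
  )
}

#' Full per-product report: transform, fit, classify
#'
#' Runs the whole pipeline on one product's monthly index series: annualized
#' inflation, descriptive statistics, (optionally IC-based structure
#' selection, otherwise the supplied structure), maximum-likelihood fit,
#' smoothed-probability regime classification and break dates, and a
#' formatted estimate table. Estimation failures (e.g. a constant series)
#' are captured as a structured failure in the report rather than an error.
#'
#' @param product Product name used to label the report.
#' @param cpi A [cpi_series()] of monthly index levels.
#' @param spec An [ms_spec()]; ignored when `selection` is given.
#' @param selection Optional list of arguments to [select_spec()] (e.g.
#'   `list(max_ar = 2, variance_options = "both")`); the BIC choice is
#'   refitted with standard errors.
#' @param starts,seed Passed to [ms_fit()].
#' @param threshold Smoothed-probability cut-off for [classify_regimes()].
#' @param se_kind Standard-error flavour for [ms_fit()].
#' @param dec Decimal mark for the formatted table.
#' @return An object of class `ms_report`: list with `product`, `stats`,
#'   `fit` (`NULL` on failure), `error` (message or `NULL`), `classification`,
#'   `breaks`, `table`, `selection`.
#' @export
build_report <- function(product, cpi, spec = ms_spec(), selection = NULL,
                         starts = 8L, seed = 1L, threshold = 0.5,
                         se_kind = "robust", dec = ".") {
  infl <- annualized_inflation(cpi)
  stats_row <- descriptive_stats(infl)
  sel <- NULL
  fit <- tryCatch({
    if (!is.null(selection)) {
      sel <- do.call(select_spec, c(list(y = infl), selection,
                                    list(starts = starts, seed = seed)))
      spec <- sel$best_bic
    }
    ms_fit(infl, spec, starts = starts, seed = seed, se_kind = se_kind)
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(product = product, inflation = infl,
                          stats = stats_row, fit = NULL,
                          error = conditionMessage(fit), classification = NULL,
                          breaks = NULL, table = NULL, selection = sel),
                     class = "ms_report"))
  }
  cls <- classify_regimes(fit$probs, threshold = threshold)
  structure(list(product = product, inflation = infl, stats = stats_row,
                 fit = fit, error = NULL, classification = cls,
                 breaks = cls$breaks,
                 table = format_estimates(fit, dec = dec), selection = sel),
            class = "ms_report")
}

#' @export
print.ms_report <- function(x, ...) {
  cat("== Report:", x$product, "==\n")
  cat("descriptive statistics (decimal fractions):\n")
  print(x$stats, row.names = FALSE)
  if (!is.null(x$error)) {
    cat("estimation FAILED:", x$error, "\n")
    return(invisible(x))
  }
  cat("\nestimates:\n")
  print(x$table, row.names = FALSE)
  if (nrow(x$breaks)) {
    cat("\nregime breaks:\n")
    print(x$breaks, row.names = FALSE)
  } else cat("\nno regime breaks detected\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, standard errors, likelihood, information criteria,
#' durations and convergence metadata; probabilities go to CSV via
#' [write_probs_csv()] instead.
#'
#' @param fit An `ms_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    spec = list(n_states = 2L,
                switching_variance = fit$spec$switching_variance,
                ar_order = fit$spec$ar_order),
    params = list(p11 = fit$params$p11, p22 = fit$params$p22,
                  mu = fit$params$mu, sigma = fit$params$sigma,
                  phi = fit$params$phi),
    se = if (is.null(fit$se)) NULL else as.list(fit$se),
    loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
    n_obs = fit$n_obs, n_params = fit$n_params,
    durations = as.list(fit$durations),
    converged = fit$converged, se_kind = fit$se_kind,
    warnings = fit$warnings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write regime probabilities to CSV
#'
#' Columns `date`, `predicted`, `filtered`, `smoothed`: the probability of
#' the low-inflation regime each month (the series plotted against the
#' inflation path in regime-probability figures).
#'
#' @param probs An `ms_probs` (with smoothed probabilities for the
#'   `smoothed` column; blank otherwise).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probs_csv <- function(probs, path) {
  n <- nrow(probs$filtered)
  months <- if (!is.null(probs$start)) {
    key0 <- probs$start[1] * 12L + probs$start[2] - 1L
    keys <- key0 + seq_len(n) - 1L
    sprintf("%04d-%02d", keys %/% 12L, keys %% 12L + 1L)
  } else as.character(seq_len(n))
  df <- data.frame(date = months,
                   predicted = probs$predicted[, "low"],
                   filtered = probs$filtered[, "low"],
                   smoothed = if (is.null(probs$smoothed)) NA else probs$smoothed[, "low"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot inflation path and low-regime probability
#'
#' Two stacked panels in the layout of the published figures: the annualized
#' inflation series on top, the smoothed probability of the low-inflation
#' regime below, with break months marked.
#'
#' @param report An `ms_report` with a successful fit.
#' @param ... Passed to [plot()].
#' @return The report, invisibly.
#' @export
plot_report <- function(report, ...) {
  if (is.null(report$fit)) stop("report has no successful fit to plot")
  probs <- report$fit$probs
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  ar <- report$fit$spec$ar_order
  yv <- as.numeric(report$inflation)
  yv <- yv[(ar + 1L):length(yv)]          # align with filtered window
  tt <- seq_along(yv)
  graphics::plot(tt, 100 * yv, type = "l", xlab = "",
                 ylab = "annualized inflation (%)", main = report$product, ...)
  graphics::abline(h = 100 * report$fit$params$mu, lty = 3, col = "grey40")
  graphics::plot(tt, probs$smoothed[, "low"], type = "l", xlab = "month",
                 ylab = "P(low regime)", ylim = c(0, 1))
  graphics::abline(v = report$breaks$index, lty = 2)
  invisible(report)
}
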