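---
title: "Regime switching in annualized food-price inflation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regime switching in annualized food-price inflation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msinfl)
```

## The question and the data

When a government puts an excise tax on sugary drinks and energy-dense
foods — as Mexico did in January 2014 with a peso-per-litre tax on sweetened
beverages and an 8% ad-valorem tax on foods above 275 kcal/100 g — the policy
question is not only *whether* the tax shows up in market prices but *how*:
does the inflation rate of the taxed products jump to a new regime, how long
does it stay there, and does it come back? `msinfl` frames this as a hidden
two-regime problem on the annualized inflation of monthly consumer-price-index
(CPI) series.

The raw input is a monthly index level $p_t$ per product. The modelled
variable is year-over-year inflation,

$$\pi_t = \frac{p_t}{p_{t-12}} - 1,$$

kept internally as a decimal fraction; percent appears only at the reporting
layer. The transform eats the first 12 index months, so a seven-year analysis
window (e.g. 84 inflation observations needs 96 index months; 72 observations
need 84). Month arithmetic is purely positional on a gap-free monthly grid:
`read_cpi_csv()` refuses series with missing or duplicated months rather than
imputing, because no defensible imputation rule exists for policy-event data.

## The model

Inflation follows a two-state Gaussian Markov-switching process
(low-inflation regime $s=1$, high-inflation regime $s=2$):

$$\pi_t = \mu_{s_t} + \varepsilon_t, \qquad
  \varepsilon_t \sim \mathcal{N}(0, \sigma_{s_t}^2),$$

with latent regimes driven by a first-order chain with transition matrix

$$P = \begin{pmatrix} p_{11} & 1-p_{11} \\ 1-p_{22} & p_{22} \end{pmatrix}.$$

The variance may be shared ($\sigma_1=\sigma_2$, 5 free parameters) or
regime-specific (6 parameters). The expected sojourn (persistence) of regime
$i$ is $1/(1-p_{ii})$ months. An optional non-switching autoregression is
supported in Hamilton's mean-adjusted form,

$$\pi_t - \mu_{s_t} = \sum_{i=1}^{q} \phi_i (\pi_{t-i} - \mu_{s_{t-i}}) +
\varepsilon_t,$$

so that $\mu_s$ remains the regime mean rather than an intercept. This
requires filtering on the joint state $(s_t,\dots,s_{t-q})$ with $2^{q+1}$
configurations; the first $q$ observations act as regressors only
(conditional likelihood). The headline model everywhere is the mean-only
$q=0$ form.

## Likelihood, filtering, smoothing

`hamilton_filter()` runs the standard forward recursion: predict the regime
distribution one step ahead through $P$, multiply by the Gaussian emission
density, normalise. The per-step normalising constants are the one-step
predictive densities, so their logs sum to the exact log marginal likelihood
$L(\theta)=\sum_t \ln f(\pi_t \mid \pi_{t-1},\theta)$, and the normalisation
doubles as an underflow guard on long series. The initial regime is drawn
from the stationary distribution of $P$,
$(1-p_{22},\,1-p_{11})/(2-p_{11}-p_{22})$ — the conventional choice for an
ergodic chain; the recursion is implemented in C++ because model selection
and simulation studies evaluate it hundreds of thousands of times.

`kim_smoother()` adds the backward pass giving $P(s_t \mid \pi_{1:T})$, the
quantity plotted as "probability of the low-inflation regime"; the final
month's smoothed and filtered probabilities coincide by construction.

Both recursions are validated against an independent oracle,
`brute_force_loglik()` / `brute_force_posterior()`, which enumerate all
$2^T$ regime paths explicitly (feasible for $T \le 14$). The test suite
checks agreement to $10^{-8}$ over 50 random parameter draws covering both
variance structures and AR orders 0–2.

## Estimation

`ms_fit()` maximises the likelihood in a transformed space — logit for
$p_{11},p_{22}$, $\log(\sigma - 10^{-6})$ for the standard deviations
(placing a hard floor of $10^{-6}$ under $\sigma$ so a point mass cannot
send the likelihood to infinity), identity for $\mu$ and $\phi$ — which
keeps every iterate interior and the Hessian usable. Switching likelihoods
are multimodal (label switching plus genuine local optima), so the default
is 8 BFGS starts: regime means at the data's (25%, 75%) and (10%, 90%)
quantiles crossed with stay-probabilities $\{0.9, 0.95\}$, the second four
perturbed by seeded noise. Convergence uses a relative objective tolerance
of $10^{-12}$ inside each BFGS run; the reported optimum is the best
converged start, and an error is raised only if *no* start converges.
Estimates are canonically ordered so regime 1 is the lower mean — matching
the labelling of the low-inflation state — which also makes refits from
permuted starts comparable. A fit near the $\sigma$ floor is flagged with a
warning rather than silently accepted.

Standard errors come from `standard_errors()`: the `"hessian"` kind inverts
the negative numerical Hessian of the log-likelihood; the default
`"robust"` kind is the sandwich $H^{-1}(S^\top S)H^{-1}$ with numerically
differentiated per-observation scores $S$ (the per-month conditional
log-densities fall directly out of the filter). Both are computed in the
transformed space and mapped to the natural scale — including the expected
durations, which are nonlinear in $p_{ii}$ — by the delta method. A
condition-number guard (`rcond < 1e-10`) turns an unidentified model (e.g.
equal regime means) into an explicit singular-Hessian error. Whether
published "robust" errors in this literature are sandwich or OPG-only is
rarely stated; both ingredients are available here and the sandwich is the
default.

## Model selection

`select_spec()` fits every candidate structure (AR order $0..q_{\max}$
crossed with shared/switching variance) and ranks converged candidates by
AIC ($-2\ell + 2k$) and BIC ($-2\ell + k\ln n$). Information criteria are
only comparable on a common sample, so all candidates are evaluated on the
observations remaining after dropping the first $q_{\max}$ points; a
lower-order candidate receives the dropped points back as lags only. Ties
break toward fewer parameters. Because variance switching is often the
substantively interesting question, the BIC table is accompanied by a
likelihood-ratio p-value for $\sigma_1=\sigma_2$ at the BIC-chosen AR order
— a diagnostic, not the headline selection, since it is not clear that
published variance-switching choices were significance-based rather than
IC-based.

## The synthetic-data generator

Real INPC product series are public but not redistributable with the
package, so the whole pipeline is exercised on simulated data whose
generative structure is exactly the model above: `simulate_regime_path()`
iterates the chain, `simulate_inflation()` adds Gaussian noise, and
`simulate_cpi_from_inflation()` rebuilds a consistent index (12 base months
at `base_index`, then $p_t = p_{t-12}(1+\pi_t)$) so that the CPI-to-inflation
transform is tested as an exact round trip (to $10^{-12}$).

The generator's default conditions are the published product-level
estimates themselves: `ms_preset()` exposes the 19 product columns (regime
means roughly 0–5% in the low and 4–15% in the high regime, self-transition
probabilities 0.88–0.99, and five products with regime-specific sigmas),
stored exactly as printed, with no back-solving of rounded values. One root
seed drives two independent sub-streams (path, noise), so changing only the
sigmas leaves the regime path untouched — the controlled-experiment
property the selection simulations rely on. $\sigma = 0$ is allowed in
simulation (noiseless fixtures with exactly $\pi_t=\mu_{s_t}$) though never
in estimation.

What the generator deliberately does *not* emulate: anticipation effects
(inflation moving before a tax takes effect), gradual month-by-month
pass-through, seasonality, and serial dependence within a regime (unless an
AR preset is constructed by hand). Passing tests therefore demonstrate that
the estimation machinery recovers the truth *when the model is true*; they
say nothing about misspecification on real series, where breaks may be
anticipatory and variance may drift.

## Validation problem sizes and numerical choices

The simulation checks use sizes chosen as the smallest at which the
asymptotic guarantees visibly bite:

* **Parameter recovery**: $T=600$ months from the `refrescos` (shared
  variance) and `pan_dulce` (switching variance) presets, 8 starts; means
  recovered within $\pm 0.005$, sigmas within $\pm 0.002$, self-transition
  probabilities within $\pm 0.03$. At the high regime's stationary share
  ($\approx 14\%$ for refrescos) these tolerances are on the order of two
  standard errors, i.e. tight but honest.
* **Selection consistency**: 50 replicates per scenario at $T=300$ with 4
  starts; BIC must pick the generating variance structure (shared
  refrescos-type vs. a variant with a $3\times$ sigma ratio) in at least
  90% of replicates.
* **Oracle agreement**: $T \le 12$ for likelihoods, $T \le 10$ for smoothed
  marginals, 50 seeded draws, tolerance $10^{-8}$.
* **Statistical conventions**: sample standard deviation; moment skewness
  $g_1$; *Pearson* (non-excess) kurtosis, so a Gaussian series reads
  $\approx 3$ — the convention under which the published descriptive tables
  (values clustering in 2–4.2) are coherent. A constant series reports
  skewness 0 by convention and kurtosis `NA`.
* **Information criteria**: $k=5$ (shared) or $k=6$ (switching), $n$ = the
  number of inflation observations entering the likelihood (72 in the
  published tables, which the AIC/BIC identities confirm for every one of
  the 19 columns).
* **Classification**: months with smoothed $P(s=\text{high}) > 0.5$ are
  labelled high; exactly 0.5 stays low. Break dates are label changes; with
  far-separated regimes the detected break lands on the simulated switch
  month exactly.
* **Locale**: internal artifacts always use decimal points; decimal-comma
  output (the published tables' locale) is an opt-in formatting flag.

## Known limitations

Two regimes only, first-order chain, constant transition probabilities, no
exogenous regressors, no Bayesian/MCMC route, and no bootstrap test for the
*number* of regimes — the likelihood-ratio surface for that question is
non-standard and out of scope. Expected-duration standard errors are
delta-method approximations and become unreliable when $p_{ii}$ approaches
1 (durations are then nearly unidentified in short samples, visible in
their large standard errors). Published duration cells can differ slightly
from $1/(1-\hat p_{ii})$ computed from the *printed* probabilities because
tables round; this package always reports durations from its own unrounded
estimates.
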