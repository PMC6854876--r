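#include <Rcpp.h>
using namespace Rcpp;

// Forward (Hamilton) filter for a 2-regime Gaussian Markov-switching model,
// optionally with a non-switching mean-adjusted AR(p) part:
//   y_t - mu[s_t] = sum_i phi[i] * (y_{t-i} - mu[s_{t-i}]) + eps,  eps ~ N(0, sigma[s_t]^2)
// The AR case runs on the expanded joint state (s_t, ..., s_{t-p}) with
// M = 2^(p+1) states; bit k of the state index is the regime of s_{t-k}
// (0 = low, 1 = high). The first p observations act as regressors only;
// the initial joint state distribution is the stationary chain rolled
// forward over the first p+1 regimes. Each step is normalised by the
// one-step predictive density, which both yields the log-likelihood
// contributions and prevents underflow on long series.

// [[Rcpp::export]]
List ms_filter_cpp(NumericVector y, double p11, double p22,
                   NumericVector mu, NumericVector sigma, NumericVector phi) {
  const int T = y.size();
  const int p = phi.size();
  const int M = 1 << (p + 1);
  const int Teff = T - p;
  if (Teff < 1) stop("series too short for AR order %d", p);
  if (!(p11 >= 0.0 && p11 <= 1.0 && p22 >= 0.0 && p22 <= 1.0))
    stop("transition probabilities must lie in [0, 1]");
  if (!(sigma[0] > 0.0 && sigma[1] > 0.0))
    stop("regime standard deviations must be strictly positive");
  const double p12 = 1.0 - p11, p21 = 1.0 - p22;
  const double denom = p12 + p21;
  if (!(denom > 0.0))
    stop("reducible chain: p11 = p22 = 1 has no unique stationary distribution");
  const double pi_low = p21 / denom;   // stationary P(s = low)
  const double pi_high = p12 / denom;

  std::vector<double> pred(M), filt(M), nxt(M);
  for (int m = 0; m < M; ++m) {            // joint prior of (s_{t0},...,s_{t0-p})
    double pr = ((m >> p) & 1) ? pi_high : pi_low;
    for (int k = p; k >= 1; --k) {
      const int from = (m >> k) & 1, to = (m >> (k - 1)) & 1;
      pr *= from == 0 ? (to == 0 ? p11 : p12) : (to == 0 ? p21 : p22);
    }
    pred[m] = pr;
  }

  NumericMatrix predm(Teff, 2), filtm(Teff, 2);
  NumericMatrix predj(Teff, M), filtj(Teff, M);
  NumericVector condll(Teff);
  const double inv_sqrt2pi = 0.3989422804014326779;
  double ll = 0.0;
  const int mask = (1 << p) - 1;

  for (int t = p; t < T; ++t) {
    const int r = t - p;
    double ct = 0.0;
    for (int m = 0; m < M; ++m) {
      const int s0 = m & 1;
      double mean = mu[s0];
      for (int i = 1; i <= p; ++i)
        mean += phi[i - 1] * (y[t - i] - mu[(m >> i) & 1]);
      const double sd = sigma[s0];
      const double z = (y[t] - mean) / sd;
      const double dens = inv_sqrt2pi / sd * std::exp(-0.5 * z * z);
      predj(r, m) = pred[m];
      filt[m] = pred[m] * dens;
      ct += filt[m];
    }
    if (!(ct > 0.0) || !std::isfinite(ct))
      stop("non-finite predictive density at observation %d (sigma underflow?)", t + 1);
    condll[r] = std::log(ct);
    ll += condll[r];
    double f_low = 0.0, f_high = 0.0, q_low = 0.0, q_high = 0.0;
    for (int m = 0; m < M; ++m) {
      filt[m] /= ct;
      filtj(r, m) = filt[m];
      if (m & 1) { f_high += filt[m]; q_high += predj(r, m); }
      else       { f_low  += filt[m]; q_low  += predj(r, m); }
    }
    filtm(r, 0) = f_low; filtm(r, 1) = f_high;
    predm(r, 0) = q_low; predm(r, 1) = q_high;

    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (int m = 0; m < M; ++m) {
      const int s0 = m & 1;
      const int shifted = (m & mask) << 1;
      const double to_low  = s0 == 0 ? p11 : p21;
      const double to_high = s0 == 0 ? p12 : p22;
      nxt[shifted]     += filt[m] * to_low;
      nxt[shifted | 1] += filt[m] * to_high;
    }
    pred = nxt;
  }

  return List::create(_["loglik"] = ll, _["condloglik"] = condll,
                      _["predicted"] = predm, _["filtered"] = filtm,
                      _["pred_joint"] = predj, _["filt_joint"] = filtj,
                      _["n_joint"] = M);
}
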