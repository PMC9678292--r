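// Sample-by-sample cores for the adaptive noise cancellers.  These loops
// run once per sample over minutes of signal, so they are compiled; the
// pure-R forward_pass/backward_update/dnf_step are the reference
// implementation and the two are tested for exact agreement.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Online deep-neural-filter loop.
// d: delayed conditioned inner channel; x: conditioned noise reference.
// weights: list of per-layer matrices (layer l: sizes[l] x fan_in[l]),
// fan_in[0] = ntaps.  Output-layer delta is e itself unless
// output_derivative.  Weight-distance logged every log_every samples.
// [[Rcpp::export]]
List dnf_core(const arma::vec& d, const arma::vec& x, List weights,
              double eta, bool output_derivative, int log_every) {
  const int n = d.n_elem;
  if ((int)x.n_elem != n) stop("d and x must have equal length");
  const int nl = weights.size();
  std::vector<arma::mat> W(nl), W0(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = as<arma::mat>(weights[l]);
    W0[l] = W[l];
  }
  const int ntaps = W[0].n_cols;

  arma::vec taps(ntaps, arma::fill::zeros);
  std::vector<arma::vec> a(nl), z(nl), delta(nl);
  arma::vec e(n), y(n);
  const int nlog = n / log_every;
  arma::mat wdist(nlog, nl, arma::fill::zeros);

  for (int i = 0; i < n; ++i) {
    // push into the delay line, newest first
    for (int k = ntaps - 1; k > 0; --k) taps[k] = taps[k - 1];
    taps[0] = x[i];

    // forward
    const arma::vec* prev = &taps;
    for (int l = 0; l < nl; ++l) {
      z[l] = W[l] * (*prev);
      a[l] = arma::tanh(z[l]);
      prev = &a[l];
    }
    const double yi = a[nl - 1][0];
    const double ei = d[i] - yi;
    y[i] = yi;
    e[i] = ei;

    // backward: delta at output is the error sample itself (published rule)
    if (output_derivative)
      delta[nl - 1] = ei * (1.0 - arma::square(a[nl - 1]));
    else
      delta[nl - 1] = arma::vec(1, arma::fill::value(ei));
    for (int l = nl - 2; l >= 0; --l)
      delta[l] = (W[l + 1].t() * delta[l + 1]) % (1.0 - arma::square(a[l]));

    // update: W^l += eta * delta^l (a^{l-1})^T, a^0 = taps
    W[0] += eta * delta[0] * taps.t();
    for (int l = 1; l < nl; ++l)
      W[l] += eta * delta[l] * a[l - 1].t();

    if ((i + 1) % log_every == 0) {
      const int r = (i + 1) / log_every - 1;
      for (int l = 0; l < nl; ++l)
        wdist(r, l) = std::sqrt(arma::accu(arma::square(W[l] - W0[l])));
    }
    if (!std::isfinite(ei))
      stop("numeric error: non-finite output at sample %d", i + 1);
  }

  List Wout(nl);
  for (int l = 0; l < nl; ++l) Wout[l] = W[l];
  return List::create(_["e"] = e, _["y"] = y, _["weights"] = Wout,
                      _["weight_distance"] = wdist);
}

// Standard LMS-adaptive FIR loop with the same tap/delay geometry.
// y = w . taps; e = d - y; w += mu * e * taps.
// [[Rcpp::export]]
List lms_core(const arma::vec& d, const arma::vec& x, arma::vec w,
              double mu) {
  const int n = d.n_elem;
  if ((int)x.n_elem != n) stop("d and x must have equal length");
  const int ntaps = w.n_elem;
  arma::vec taps(ntaps, arma::fill::zeros);
  arma::vec e(n), y(n);
  for (int i = 0; i < n; ++i) {
    for (int k = ntaps - 1; k > 0; --k) taps[k] = taps[k - 1];
    taps[0] = x[i];
    const double yi = arma::dot(w, taps);
    const double ei = d[i] - yi;
    y[i] = yi;
    e[i] = ei;
    w += mu * ei * taps;
    if (!std::isfinite(ei))
      stop("numeric error: non-finite output at sample %d (LMS unstable?)",
           i + 1);
  }
  return List::create(_["e"] = e, _["y"] = y, _["weights"] = w);
}
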