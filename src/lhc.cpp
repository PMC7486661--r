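// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec &u, double theta, double delta) {
  return 1.0 / (1.0 + arma::exp(-(u - theta) / delta));
}

// Wave-evoked V1 responses with one-step-delayed recurrent horizontal input:
//   r_t = sigmoid( drive_t + W' r_{t-1} ), r_{-1} = 0.
// drive is n_sites x T (frozen feedforward input); W(i,j) is the weight i->j.
// [[Rcpp::export]]
arma::mat recurrent_response_cpp(const arma::mat &drive, const arma::mat &W,
                                 double theta, double delta) {
  const arma::uword n = drive.n_rows, T = drive.n_cols;
  arma::mat R(n, T);
  arma::vec r_prev(n, arma::fill::zeros);
  arma::mat Wt = W.t();
  for (arma::uword t = 0; t < T; ++t) {
    r_prev = sigmoid(drive.col(t) + Wt * r_prev, theta, delta);
    R.col(t) = r_prev;
  }
  return R;
}

// Covariance-rule training of the horizontal network over a sequence of
// waves. For each wave: run the recurrence, take each site's peak response,
// update dW(i,j) = eps * p_i * (p_j - Rbar_j) against the running-average
// learning threshold Rbar (EMA, time constant tau, initialised at the first
// sampled peak), then clip to [0, cap] and zero the diagonal.
// With single = true the within-wave recurrence runs in single precision
// (weights and updates stay double); cuts the dominant matvec cost ~2x.
// [[Rcpp::export]]
List lhc_train_cpp(arma::mat W, arma::vec Rbar, bool seen,
                   const List &drives, const IntegerVector &order,
                   double eps, double tau, double cap,
                   double theta, double delta, bool single = false) {
  const arma::uword n = W.n_rows;
  arma::vec r_prev(n), u(n), peak(n);
  arma::fvec rf(n), uf(n), pf(n);
  const float thetaf = (float)theta, deltaf = (float)delta;
  for (int w = 0; w < order.size(); ++w) {
    const arma::mat drive = as<arma::mat>(drives[order[w] - 1]);
    const arma::uword T = drive.n_cols;
    peak.fill(-1.0);
    if (single) {
      arma::fmat Wtf = arma::conv_to<arma::fmat>::from(W.t());
      arma::fmat drivef = arma::conv_to<arma::fmat>::from(drive);
      rf.zeros();
      pf.fill(-1.0f);
      for (arma::uword t = 0; t < T; ++t) {
        uf = drivef.col(t) + Wtf * rf;
        rf = 1.0f / (1.0f + arma::exp(-(uf - thetaf) / deltaf));
        for (arma::uword k = 0; k < n; ++k) if (rf[k] > pf[k]) pf[k] = rf[k];
      }
      peak = arma::conv_to<arma::vec>::from(pf);
    } else {
      arma::mat Wt = W.t();
      r_prev.zeros();
      for (arma::uword t = 0; t < T; ++t) {
        u = drive.col(t) + Wt * r_prev;
        r_prev = sigmoid(u, theta, delta);
        // strict > keeps the earliest time on ties
        for (arma::uword k = 0; k < n; ++k) if (r_prev[k] > peak[k]) peak[k] = r_prev[k];
      }
    }
    if (!seen) { Rbar = peak; seen = true; }
    arma::vec dev = peak - Rbar;
    W += eps * (peak * dev.t());
    W = arma::clamp(W, 0.0, cap);
    W.diag().zeros();
    Rbar = (1.0 - 1.0 / tau) * Rbar + (1.0 / tau) * peak;
  }
  return List::create(_["W"] = W, _["Rbar"] = Rbar, _["seen"] = seen);
}
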