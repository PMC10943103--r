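// Replay-training inner loops. One-hot (discrete) transitions update single
// columns of Q and V; W always receives a rank-1 delta-rule update from the
// dense state difference. Kept in C++ because the benchmark sweeps apply
// tens of thousands of rank-1 updates to 1000-dimensional states.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void normalize_col(arma::mat &V, arma::uword j) {
  double n = arma::norm(V.col(j));
  if (n > 0) V.col(j) /= n;
}

// [[Rcpp::export(rng = false)]]
List train_replay_onehot(arma::mat Q, arma::mat V, arma::mat W,
                         const arma::uvec &from, const arma::uvec &act,
                         const arma::uvec &to, int rounds,
                         double eta_q, double eta_v, double eta_w,
                         bool normalize_v, bool w_regression) {
  const arma::uword T = from.n_elem;
  arma::vec curve(rounds, arma::fill::zeros);
  arma::vec err(Q.n_rows), ds(Q.n_rows);
  for (int r = 0; r < rounds; ++r) {
    double sse = 0.0;
    for (arma::uword t = 0; t < T; ++t) {
      const arma::uword i = from[t] - 1, a = act[t] - 1, j = to[t] - 1;
      err = Q.col(j) - Q.col(i) - V.col(a);      // s_{t+1} - s_hat
      sse += arma::dot(err, err);
      if (!err.is_finite()) stop("non-finite prediction error at step %d",
                                 (int)t + 1);
      if (eta_w != 0) {
        ds = Q.col(j) - Q.col(i);
        if (w_regression) {
          arma::vec wa = -(W * ds);              // a_t - W ds, sparse part below
          wa[a] += 1.0;
          W += eta_w * wa * ds.t();
        } else {
          W.row(a) += eta_w * (ds.t() - W.row(a));
        }
      }
      V.col(a) += eta_v * err;
      Q.col(j) -= eta_q * err;
      if (normalize_v) normalize_col(V, a);
    }
    curve[r] = sse / (double)T;
  }
  return List::create(_["Q"] = Q, _["V"] = V, _["W"] = W,
                      _["curve"] = curve);
}

// Dense-observation variant (continuous environments). Observations are
// columns of O and Onext; optionally regularizes t(Q) to reconstruct o_t.
// [[Rcpp::export(rng = false)]]
List train_replay_dense(arma::mat Q, arma::mat V, arma::mat W,
                        const arma::mat &O, const arma::uvec &act,
                        const arma::mat &Onext, int rounds,
                        double eta_q, double eta_v, double eta_w,
                        bool normalize_v, bool w_regression,
                        double eta_recon) {
  const arma::uword T = act.n_elem;
  arma::vec curve(rounds, arma::fill::zeros);
  for (int r = 0; r < rounds; ++r) {
    double sse = 0.0;
    for (arma::uword t = 0; t < T; ++t) {
      const arma::uword a = act[t] - 1;
      arma::vec o = O.col(t), onext = Onext.col(t);
      arma::vec s = Q * o, snext = Q * onext;
      arma::vec err = snext - s - V.col(a);
      arma::vec ds = snext - s;
      sse += arma::dot(err, err);
      if (!err.is_finite()) stop("non-finite prediction error at step %d",
                                 (int)t + 1);
      if (eta_w != 0) {
        if (w_regression) {
          arma::vec wa = -(W * ds);
          wa[a] += 1.0;
          W += eta_w * wa * ds.t();
        } else {
          W.row(a) += eta_w * (ds.t() - W.row(a));
        }
      }
      V.col(a) += eta_v * err;
      Q -= eta_q * err * onext.t();
      if (eta_recon != 0) {
        arma::vec rerr = o - Q.t() * s;          // reconstruction error
        Q += eta_recon * s * rerr.t();
      }
      if (normalize_v) normalize_col(V, a);
    }
    curve[r] = sse / (double)T;
  }
  return List::create(_["Q"] = Q, _["V"] = V, _["W"] = W,
                      _["curve"] = curve);
}
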