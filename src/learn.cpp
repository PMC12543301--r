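// Trial-level delta-rule prediction and truncated-normal likelihood.
//
// Cells are the 8 session x agent x ability combinations in canonical order
// (T1 before T2, Self before Other, High before Low); trials must arrive
// sorted by cell then trial so each cell forms one contiguous block. The
// latent expectation starts at the cell's starting value and is updated as
//   EXP <- EXP + alpha * PE * (1 - w * ND(FB)),
// where ND is the relative normal density of the feedback percentile around
// 50 (peak scaled to 1). Mean-model cells predict a constant instead.

#include <Rcpp.h>
using namespace Rcpp;

static inline double nd_rel(double fb, double sigma_nd) {
  double z = (fb - 50.0) / sigma_nd;
  return std::exp(-0.5 * z * z);
}

static inline double lp_trunc_norm(double x, double mu, double sd) {
  double z = R::pnorm(100.0, mu, sd, 1, 0) - R::pnorm(0.0, mu, sd, 1, 0);
  return R::dnorm(x, mu, sd, 1) - std::log(z);
}

// Predicted (pre-update) expectation per trial for one parameter vector.
// amap: 8 x 2 matrix of 1-based alpha indices (cols: PE > 0, PE < 0);
// svmap: 8 1-based indices into sv; wcell: per-cell discounting weight.
// mean_model: predictions are sv[svmap[cell]] with no updating.
// [[Rcpp::export(name = ".predict_cpp")]]
NumericVector predict_cpp(IntegerVector cell, NumericVector fb,
                          IntegerMatrix amap, IntegerVector svmap,
                          NumericVector wcell, NumericVector alpha,
                          NumericVector sv, double sigma_nd, bool mean_model) {
  int n = cell.size();
  NumericVector pred(n);
  double latent = 0.0;
  int prev = -1;
  for (int i = 0; i < n; ++i) {
    int c = cell[i] - 1;
    if (mean_model) {
      pred[i] = sv[svmap[c] - 1];
      continue;
    }
    if (cell[i] != prev) {
      latent = sv[svmap[c] - 1];
      prev = cell[i];
    }
    pred[i] = latent;
    double pe = fb[i] - latent;
    if (pe != 0.0) {
      double a = alpha[amap(c, pe > 0.0 ? 0 : 1) - 1];
      latent += a * pe * (1.0 - wcell[c] * nd_rel(fb[i], sigma_nd));
    }
  }
  return pred;
}

// Pointwise log-likelihood matrix over posterior draws (draws x trials).
// alpha_d: S x n_alpha (0 columns for the mean model); w_d: S x 2 session
// weights (all zero when the model has no discounting); sv_d: S x n_sv;
// sigma_d: S observation noises. cell_session: 1-based session per cell.
// [[Rcpp::export(name = ".loglik_draws_cpp")]]
NumericMatrix loglik_draws_cpp(IntegerVector cell, NumericVector fb,
                               NumericVector obs, IntegerMatrix amap,
                               IntegerVector svmap, IntegerVector cell_session,
                               NumericMatrix alpha_d, NumericMatrix w_d,
                               NumericMatrix sv_d, NumericVector sigma_d,
                               double sigma_nd, bool mean_model) {
  int n = cell.size();
  int S = sigma_d.size();
  NumericMatrix out(S, n);
  for (int s = 0; s < S; ++s) {
    double latent = 0.0;
    int prev = -1;
    double sigma = sigma_d[s];
    for (int i = 0; i < n; ++i) {
      int c = cell[i] - 1;
      double pred;
      if (mean_model) {
        pred = sv_d(s, svmap[c] - 1);
      } else {
        if (cell[i] != prev) {
          latent = sv_d(s, svmap[c] - 1);
          prev = cell[i];
        }
        pred = latent;
        double pe = fb[i] - latent;
        if (pe != 0.0) {
          double a = alpha_d(s, amap(c, pe > 0.0 ? 0 : 1) - 1);
          double w = w_d(s, cell_session[c] - 1);
          latent += a * pe * (1.0 - w * nd_rel(fb[i], sigma_nd));
        }
      }
      out(s, i) = lp_trunc_norm(obs[i], pred, sigma);
    }
  }
  return out;
}
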