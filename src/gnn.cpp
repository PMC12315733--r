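// Training-step kernel: loss and analytic gradients of the GCN+MLP edge
// regressor for a batch of subjects. Mirrors the R reference implementation
// (gnn_loss_grad) exactly; that version is kept as the oracle in tests.
//
// The decoder pass is fused over ordered pairs: per-pair work uses
// contiguous column views of transposed (features x nodes) matrices and
// accumulates straight into the K-sized gradient buffers, so no
// (n_pairs x width) temporary is ever materialized.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void prelu_mat(arma::mat& x, double alpha) {
  double* p = x.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword k = 0; k < n; ++k) {
    if (p[k] < 0) p[k] *= alpha;
  }
}

// [[Rcpp::export(name = ".gnn_loss_grad_cpp")]]
List gnn_loss_grad_cpp(List S_list, List efc_list, List Wg_list,
                       arma::vec alpha, arma::mat W1, arma::vec b1,
                       arma::vec w2, double b2, double lambda,
                       arma::uvec ii, arma::uvec jj, arma::uvec perm_ji,
                       int K) {
  const int L = Wg_list.size();
  const int nb = S_list.size();
  const arma::uword P = ii.n_elem;
  std::vector<arma::mat> Wg(L);
  for (int l = 0; l < L; ++l) Wg[l] = as<arma::mat>(Wg_list[l]);
  const int C = Wg[L - 1].n_cols;
  const int M = W1.n_cols;  // decoder hidden width
  arma::mat W1a = W1.rows(0, C - 1);
  arma::mat W1b = W1.rows(C, 2 * C - 1);

  std::vector<arma::mat> gWg(L);
  for (int l = 0; l < L; ++l) gWg[l].zeros(Wg[l].n_rows, Wg[l].n_cols);
  arma::vec galpha(L, arma::fill::zeros);
  arma::mat gW1(W1.n_rows, W1.n_cols, arma::fill::zeros);
  arma::vec gb1(M, arma::fill::zeros);
  arma::vec gw2(M, arma::fill::zeros);
  double gb2 = 0.0, loss = 0.0;

  arma::vec a1(M), da1(M);
  const double* w2p = w2.memptr();

  for (int s = 0; s < nb; ++s) {
    arma::mat S = as<arma::mat>(S_list[s]);
    arma::vec efc = as<arma::vec>(efc_list[s]);
    // forward through the GCN stack (H0 = I)
    std::vector<arma::mat> H(L + 1), Z(L);
    H[0] = arma::eye(K, K);
    for (int l = 0; l < L; ++l) {
      arma::mat SH = (l == 0) ? S : S * H[l];
      Z[l] = SH * Wg[l];
      H[l + 1] = Z[l];
      prelu_mat(H[l + 1], alpha(l));
    }
    // decoder, fused over pairs: columns of HaT/HbT are per-node features
    arma::mat HaT = (H[L] * W1a).t();           // M x K
    arma::mat HbT = (H[L] * W1b).t();           // M x K
    HbT.each_col() += b1;
    arma::mat aggT_i(M, K, arma::fill::zeros);  // column sums of dA1 by i
    arma::mat aggT_j(M, K, arma::fill::zeros);
    const double scale = 2.0 / ((double)P * nb);
    double loss_s = 0.0;
    for (arma::uword p = 0; p < P; ++p) {
      const double* ai = HaT.colptr(ii[p]);
      const double* bj = HbT.colptr(jj[p]);
      double pred = b2;
      double* a1p = a1.memptr();
      for (int m = 0; m < M; ++m) {
        double v = ai[m] + bj[m];
        a1p[m] = v;
        if (v > 0) pred += v * w2p[m];
      }
      const double resid = pred - efc[p];
      loss_s += resid * resid;
      const double dpred = scale * resid;
      gb2 += dpred;
      double* gi = aggT_i.colptr(ii[p]);
      double* gj = aggT_j.colptr(jj[p]);
      double* g2 = gw2.memptr();
      for (int m = 0; m < M; ++m) {
        if (a1p[m] > 0) {
          g2[m] += a1p[m] * dpred;
          const double d = w2p[m] * dpred;
          gi[m] += d;
          gj[m] += d;
        }
      }
    }
    loss += loss_s / P;
    arma::mat agg_i = aggT_i.t();               // K x M
    arma::mat agg_j = aggT_j.t();
    gW1.rows(0, C - 1) += H[L].t() * agg_i;
    gW1.rows(C, 2 * C - 1) += H[L].t() * agg_j;
    gb1 += arma::sum(agg_i, 0).t();
    arma::mat dH = agg_i * W1a.t() + agg_j * W1b.t();
    for (int l = L - 1; l >= 0; --l) {
      // PReLU backward + slope gradient in one pass
      const double* zp = Z[l].memptr();
      double* dp = dH.memptr();
      double ga = 0.0;
      const arma::uword n = dH.n_elem;
      const double al = alpha(l);
      for (arma::uword k = 0; k < n; ++k) {
        if (zp[k] < 0) {
          ga += dp[k] * zp[k];
          dp[k] *= al;
        }
      }
      galpha(l) += ga;
      arma::mat SH = (l == 0) ? S : S * H[l];
      gWg[l] += SH.t() * dH;
      if (l > 0) dH = S * (dH * Wg[l].t());
    }
  }
  loss = loss / nb + lambda * (arma::accu(W1 % W1) + arma::dot(w2, w2));
  gW1 += 2.0 * lambda * W1;
  gw2 += 2.0 * lambda * w2;

  List gWg_out(L);
  for (int l = 0; l < L; ++l) gWg_out[l] = gWg[l];
  return List::create(_["loss"] = loss, _["gWg"] = gWg_out,
                      _["galpha"] = galpha, _["gW1"] = gW1, _["gb1"] = gb1,
                      _["gW2"] = gw2, _["gb2"] = gb2);
}
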