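// Batched LSTM forward/backward kernels.
//
// Layout contract (shared with the R callers): sequence tensors are
// flat (B*T) x H matrices whose rows are grouped by timestep, row
// (t-1)*B + b holding pair b at position t. `mask` is B x T with 1 on
// valid positions. The masked state update h = m*h_new + (1-m)*h_prev
// carries state through right-padding (forward direction) and keeps
// it at zero before a sequence starts (backward direction).
//
// Gate math is fused into single element passes to avoid temporary
// allocations, which dominate at the small matrix sizes used here.

#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigm1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
Rcpp::List lstm_forward_cpp(const arma::mat& Xf, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b,
                            const arma::mat& mask, bool reverse,
                            bool need_cache) {
  const uword B = mask.n_rows, T = mask.n_cols;
  const uword H = U.n_rows;
  const uword n = B * T;
  mat P = Xf * W;
  P.each_row() += b.t();
  mat h(B, H, fill::zeros), cc(B, H, fill::zeros);
  mat Hout(n, H, fill::zeros);
  mat G(B, 4 * H);
  mat ci, cf, cg, co, ctc, ccs;
  if (need_cache) {
    ci.set_size(n, H); cf.set_size(n, H); cg.set_size(n, H);
    co.set_size(n, H); ctc.set_size(n, H); ccs.set_size(n, H);
  }
  for (uword s = 0; s < T; ++s) {
    uword t = reverse ? (T - 1 - s) : s;
    uword r0 = t * B;
    G = P.rows(r0, r0 + B - 1);
    G += h * U;
    const double* mv = mask.colptr(t);
    for (uword j = 0; j < H; ++j) {
      const double* gi_ = G.colptr(j);
      const double* gf_ = G.colptr(H + j);
      const double* gg_ = G.colptr(2 * H + j);
      const double* go_ = G.colptr(3 * H + j);
      double* hj = h.colptr(j);
      double* cj = cc.colptr(j);
      double* Hj = Hout.colptr(j) + r0;
      for (uword r = 0; r < B; ++r) {
        double i_ = sigm1(gi_[r]);
        double f_ = sigm1(gf_[r]);
        double g_ = std::tanh(gg_[r]);
        double o_ = sigm1(go_[r]);
        double c_new = f_ * cj[r] + i_ * g_;
        double tc = std::tanh(c_new);
        double h_new = o_ * tc;
        double m = mv[r];
        hj[r] = m * h_new + (1.0 - m) * hj[r];
        cj[r] = m * c_new + (1.0 - m) * cj[r];
        Hj[r] = hj[r];
        if (need_cache) {
          ci.colptr(j)[r0 + r] = i_;
          cf.colptr(j)[r0 + r] = f_;
          cg.colptr(j)[r0 + r] = g_;
          co.colptr(j)[r0 + r] = o_;
          ctc.colptr(j)[r0 + r] = tc;
          ccs.colptr(j)[r0 + r] = cj[r];
        }
      }
    }
  }
  if (need_cache) {
    return Rcpp::List::create(
      Rcpp::Named("H") = Hout, Rcpp::Named("i") = ci,
      Rcpp::Named("f") = cf, Rcpp::Named("g") = cg,
      Rcpp::Named("o") = co, Rcpp::Named("tc") = ctc,
      Rcpp::Named("c") = ccs);
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hout);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
Rcpp::List lstm_backward_cpp(const arma::mat& W, const arma::mat& U,
                             const arma::mat& Xf, const arma::mat& Hout,
                             const arma::mat& ci, const arma::mat& cf,
                             const arma::mat& cg, const arma::mat& co,
                             const arma::mat& ctc, const arma::mat& ccs,
                             const arma::mat& mask, bool reverse,
                             const arma::mat& dH) {
  const uword B = mask.n_rows, T = mask.n_cols;
  const uword H = U.n_rows;
  const uword n = B * T;
  mat dGflat(n, 4 * H, fill::zeros);
  mat Hprev_flat(n, H, fill::zeros);
  mat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    // iterate in reverse of the forward order
    uword t = reverse ? s : (T - 1 - s);
    sword prev_t = reverse ? (sword)t + 1 : (sword)t - 1;
    uword r0 = t * B;
    bool has_prev = prev_t >= 0 && prev_t < (sword)T;
    uword p0 = has_prev ? (uword)prev_t * B : 0;
    const double* mv = mask.colptr(t);
    for (uword j = 0; j < H; ++j) {
      const double* gi_ = ci.colptr(j) + r0;
      const double* gf_ = cf.colptr(j) + r0;
      const double* gg_ = cg.colptr(j) + r0;
      const double* go_ = co.colptr(j) + r0;
      const double* tc_ = ctc.colptr(j) + r0;
      const double* cprev_ = has_prev ? ccs.colptr(j) + p0 : nullptr;
      const double* hprev_ = has_prev ? Hout.colptr(j) + p0 : nullptr;
      const double* dHj = dH.colptr(j) + r0;
      double* dhc = dh_carry.colptr(j);
      double* dcc = dc_carry.colptr(j);
      double* dGi = dGflat.colptr(j) + r0;
      double* dGf = dGflat.colptr(H + j) + r0;
      double* dGg = dGflat.colptr(2 * H + j) + r0;
      double* dGo = dGflat.colptr(3 * H + j) + r0;
      double* Hp = Hprev_flat.colptr(j) + r0;
      for (uword r = 0; r < B; ++r) {
        double m = mv[r];
        double c_prev = has_prev ? cprev_[r] : 0.0;
        double dh_tot = dHj[r] + dhc[r];
        double dh_new = m * dh_tot;
        double dh_prev_direct = (1.0 - m) * dh_tot;
        double tc = tc_[r];
        double dc_new = m * dcc[r] + dh_new * go_[r] * (1.0 - tc * tc);
        double dc_prev_direct = (1.0 - m) * dcc[r];
        double do_ = dh_new * tc;
        double df_ = dc_new * c_prev;
        double di_ = dc_new * gg_[r];
        double dg_ = dc_new * gi_[r];
        dGi[r] = di_ * gi_[r] * (1.0 - gi_[r]);
        dGf[r] = df_ * gf_[r] * (1.0 - gf_[r]);
        dGg[r] = dg_ * (1.0 - gg_[r] * gg_[r]);
        dGo[r] = do_ * go_[r] * (1.0 - go_[r]);
        Hp[r] = has_prev ? hprev_[r] : 0.0;
        // dh_carry handled after the gemm below; store direct part
        dhc[r] = dh_prev_direct;
        dcc[r] = dc_new * gf_[r] + dc_prev_direct;
      }
    }
    // dh_carry += dG_t * U^t  (one gemm per step)
    dh_carry += dGflat.rows(r0, r0 + B - 1) * U.t();
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = Xf.t() * dGflat,
    Rcpp::Named("U") = Hprev_flat.t() * dGflat,
    Rcpp::Named("b") = sum(dGflat, 0).t(),
    Rcpp::Named("dX") = dGflat * W.t());
}
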