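// Compiled forward/backward kernels for the multi-head graph attention
// network. Mirrors the R reference implementation in R/gat.R exactly
// (tests assert agreement); used by training and bulk scoring where the
// per-graph interpreter overhead would dominate. The fused weight matrix
// W = [W_H | W_E] is applied in two blocks so the static edge-feature
// projection is computed once per layer instead of once per direction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOGIT_CLAMP = 50.0;

static inline double elu1(double x) { return x > 0 ? x : std::exp(x) - 1.0; }
static inline double elu1p(double x) { return x > 0 ? 1.0 : std::exp(x); }

struct LayerCache {
  arma::mat Hd, Hs;        // H rows gathered for dst/src (T x p)
  arma::mat Zd, Zs;        // embedded messages (T x K*h)
  arma::mat pre, L, alpha; // attention intermediates (T x K)
  arma::mat S;             // aggregated messages (n x K*h)
};

static arma::mat layer_fwd(const arma::mat& H, const arma::mat& ZE,
                           const arma::mat& WH, const arma::vec& a1,
                           const arma::vec& a2, const arma::uvec& dst,
                           const arma::uvec& src, int n_nodes, int K, int h,
                           double slope, bool linear_out, LayerCache& cc) {
  const arma::uword T = dst.n_elem;
  cc.Hd = H.rows(dst);
  cc.Hs = H.rows(src);
  cc.Zd = cc.Hd * WH.t() + ZE;
  cc.Zs = cc.Hs * WH.t() + ZE;
  cc.pre.set_size(T, K);
  for (int k = 0; k < K; ++k) {
    arma::span cols(k * h, (k + 1) * h - 1);
    cc.pre.col(k) = cc.Zd.cols(cols) * a1.subvec(k * h, (k + 1) * h - 1) +
                    cc.Zs.cols(cols) * a2.subvec(k * h, (k + 1) * h - 1);
  }
  cc.L = cc.pre;
  cc.L.transform([slope](double x) { return x > 0 ? x : slope * x; });
  arma::mat expL = arma::clamp(cc.L, -LOGIT_CLAMP, LOGIT_CLAMP);
  expL.transform([](double x) { return std::exp(x); });
  arma::mat denom(n_nodes, K, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) denom.row(dst[t]) += expL.row(t);
  cc.alpha.set_size(T, K);
  for (arma::uword t = 0; t < T; ++t)
    cc.alpha.row(t) = expL.row(t) / denom.row(dst[t]);
  cc.S.zeros(n_nodes, K * h);
  for (arma::uword t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      for (int c = 0; c < h; ++c)
        cc.S(dst[t], k * h + c) += cc.alpha(t, k) * cc.Zs(t, k * h + c);
  arma::mat Hout = cc.S;
  if (!linear_out) Hout.transform([](double x) { return elu1(x); });
  return Hout;
}

// backward through one layer; fills dW (K*h x p+q), da1, da2; returns dH
static arma::mat layer_bwd(const arma::mat& dHout, const arma::mat& Eexp,
                           const arma::mat& WH, const arma::vec& a1,
                           const arma::vec& a2, const arma::uvec& dst,
                           const arma::uvec& src, int n_nodes, int K, int h,
                           int p, double slope, bool linear_out,
                           const LayerCache& cc, arma::mat& dW,
                           arma::vec& da1, arma::vec& da2) {
  const arma::uword T = dst.n_elem;
  arma::mat dS = dHout;
  if (!linear_out) {
    for (arma::uword r = 0; r < dS.n_rows; ++r)
      for (arma::uword c = 0; c < dS.n_cols; ++c)
        dS(r, c) *= elu1p(cc.S(r, c));
  }
  arma::mat dM = dS.rows(dst);                       // T x K*h
  arma::mat dalpha(T, K, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double acc = 0;
      for (int c = 0; c < h; ++c)
        acc += dM(t, k * h + c) * cc.Zs(t, k * h + c);
      dalpha(t, k) = acc;
    }
  arma::mat dZs(T, K * h);
  for (arma::uword t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      for (int c = 0; c < h; ++c)
        dZs(t, k * h + c) = dM(t, k * h + c) * cc.alpha(t, k);
  arma::mat inner(n_nodes, K, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t)
    inner.row(dst[t]) += cc.alpha.row(t) % dalpha.row(t);
  arma::mat dL(T, K);
  for (arma::uword t = 0; t < T; ++t)
    dL.row(t) = cc.alpha.row(t) % (dalpha.row(t) - inner.row(dst[t]));
  for (arma::uword t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      if (std::abs(cc.L(t, k)) > LOGIT_CLAMP) { dL(t, k) = 0; continue; }
      dL(t, k) *= (cc.pre(t, k) > 0 ? 1.0 : slope);
    }
  arma::mat dZd(T, K * h);
  da1.zeros(K * h); da2.zeros(K * h);
  for (arma::uword t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      for (int c = 0; c < h; ++c) {
        const int col = k * h + c;
        const double dp = dL(t, k);
        dZd(t, col) = dp * a1[col];
        dZs(t, col) += dp * a2[col];
        da1[col] += dp * cc.Zd(t, col);
        da2[col] += dp * cc.Zs(t, col);
      }
  // dW = [dZs^T Hs + dZd^T Hd | (dZs + dZd)^T Eexp]
  dW = arma::join_rows(dZs.t() * cc.Hs + dZd.t() * cc.Hd,
                       (dZs + dZd).t() * Eexp);
  arma::mat dXs = dZs * WH;                          // node part only
  arma::mat dXd = dZd * WH;
  arma::mat dH(n_nodes, p, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    dH.row(src[t]) += dXs.row(t);
    dH.row(dst[t]) += dXd.row(t);
  }
  return dH;
}

// [[Rcpp::export(name = ".gat_core")]]
List gat_core(List Ws, List a1s, List a2s, const arma::mat& H0,
              const arma::mat& Eexp, const arma::uvec& dst1,
              const arma::uvec& src1, const arma::uvec& ei1,
              const arma::uvec& ej1, int n_nodes, const arma::ivec& heads,
              const arma::ivec& hidden, double slope, bool final_identity,
              bool raw_dot, bool with_grad, const arma::vec& z) {
  const int nl = Ws.size();
  const int q = Eexp.n_cols;
  arma::uvec dst = dst1 - 1, src = src1 - 1, ei = ei1 - 1, ej = ej1 - 1;
  std::vector<LayerCache> caches(nl);
  std::vector<arma::mat> WH(nl), WE(nl);
  std::vector<arma::vec> a1v(nl), a2v(nl);
  arma::mat H = H0;
  for (int l = 0; l < nl; ++l) {
    arma::mat W = as<arma::mat>(Ws[l]);
    const int p = W.n_cols - q;
    WH[l] = W.cols(0, p - 1);
    WE[l] = W.cols(p, W.n_cols - 1);
    a1v[l] = as<arma::vec>(a1s[l]);
    a2v[l] = as<arma::vec>(a2s[l]);
    bool lin = final_identity && l == nl - 1;
    arma::mat ZE = Eexp * WE[l].t();
    H = layer_fwd(H, ZE, WH[l], a1v[l], a2v[l], dst, src, n_nodes,
                  heads[l], hidden[l], slope, lin, caches[l]);
    if (!H.is_finite()) stop("non-finite embedding after layer %d", l + 1);
  }
  const arma::uword m = ei.n_elem;
  arma::vec scores(m);
  for (arma::uword e = 0; e < m; ++e) {
    double dot = arma::dot(H.row(ei[e]), H.row(ej[e]));
    scores[e] = raw_dot ? dot : 1.0 / (1.0 + std::exp(-dot));
  }
  double Q = arma::mean(scores);
  List out = List::create(_["edge_scores"] = scores, _["Q"] = Q,
                          _["embeddings"] = H);
  if (!with_grad) return out;

  double loss = arma::accu(arma::square(scores - z));
  arma::mat dH(n_nodes, H.n_cols, arma::fill::zeros);
  for (arma::uword e = 0; e < m; ++e) {
    double ds = 2.0 * (scores[e] - z[e]);
    double dprod = raw_dot ? ds : ds * scores[e] * (1.0 - scores[e]);
    dH.row(ei[e]) += dprod * H.row(ej[e]);
    dH.row(ej[e]) += dprod * H.row(ei[e]);
  }
  List gW(nl), ga1(nl), ga2(nl);
  for (int l = nl - 1; l >= 0; --l) {
    bool lin = final_identity && l == nl - 1;
    arma::mat dW; arma::vec da1, da2;
    dH = layer_bwd(dH, Eexp, WH[l], a1v[l], a2v[l], dst, src, n_nodes,
                   heads[l], hidden[l], WH[l].n_cols, slope, lin, caches[l],
                   dW, da1, da2);
    gW[l] = dW; ga1[l] = da1; ga2[l] = da2;
  }
  out["loss"] = loss;
  out["gW"] = gW; out["ga1"] = ga1; out["ga2"] = ga2;
  return out;
}
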