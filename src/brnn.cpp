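// Two-stage bidirectional recurrent network core: forward passes, the
// semi-global window filter between stages, and backpropagation through
// structure for the joint (stage-1 + stage-2) cross-entropy loss.
//
// Matrices are column-per-position internally (m x N); the R interface is
// row-per-position (N x m), transposed at the boundary.  All work that
// touches the input width d is batched into matrix-matrix products; the
// sequential recurrences only move state-width vectors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct Stage {
  mat WF1, WF2, WB1, WB2, WO1, WO2;
  vec bF1, bF2, bB1, bB2, bO1, bO2;
  int d, m, H, K, S;
};

Stage stage_from_list(const List& st) {
  Stage s;
  s.WF1 = as<mat>(st["WF1"]); s.bF1 = as<vec>(st["bF1"]);
  s.WF2 = as<mat>(st["WF2"]); s.bF2 = as<vec>(st["bF2"]);
  s.WB1 = as<mat>(st["WB1"]); s.bB1 = as<vec>(st["bB1"]);
  s.WB2 = as<mat>(st["WB2"]); s.bB2 = as<vec>(st["bB2"]);
  s.WO1 = as<mat>(st["WO1"]); s.bO1 = as<vec>(st["bO1"]);
  s.WO2 = as<mat>(st["WO2"]); s.bO2 = as<vec>(st["bO2"]);
  s.d = as<int>(st["d"]); s.m = as<int>(st["m"]);
  s.H = as<int>(st["state_width"]); s.K = as<int>(st["hidden_width"]);
  s.S = as<int>(st["span"]);
  if ((int)s.WF1.n_cols != s.d + s.S * s.H)
    stop("stage parameter shapes inconsistent with input width d");
  return s;
}

// Activation caches kept for the backward pass.  State chains carry S
// zero-padding columns (h_0^F = h_{N+1}^B = 0 extended over the span):
// HF col S+j = forward state at position j, cols 0..S-1 zero;
// HB col j = backward state at position j, cols N..N+S-1 zero.
struct StageCache {
  mat AF, AB;   // K x N transition-net hidden activations
  mat HF, HB;   // H x (N + S) state chains with padding
  mat Z;        // K x N output-net hidden
  mat O;        // m x N softmax outputs
};

void softmax_cols(mat& L) {
  for (arma::uword j = 0; j < L.n_cols; ++j) {
    vec c = L.col(j);
    c -= c.max();
    c = arma::exp(c);
    L.col(j) = c / arma::accu(c);
  }
}

void stage_forward_core(const Stage& s, const mat& X, StageCache& C) {
  const int N = X.n_cols, d = s.d, H = s.H, S = s.S;
  C.AF.set_size(s.K, N); C.AB.set_size(s.K, N);
  C.HF.zeros(H, N + S); C.HB.zeros(H, N + S);
  // input contributions to the transition nets, batched over positions
  mat PF = s.WF1.cols(0, d - 1) * X;
  PF.each_col() += s.bF1;
  mat PB = s.WB1.cols(0, d - 1) * X;
  PB.each_col() += s.bB1;
  vec acc, a;
  for (int j = 0; j < N; ++j) {
    acc = PF.col(j);
    for (int k = 1; k <= S; ++k)
      acc += s.WF1.cols(d + (k - 1) * H, d + k * H - 1) * C.HF.col(S + j - k);
    a = arma::tanh(acc);
    C.AF.col(j) = a;
    C.HF.col(S + j) = arma::tanh(s.WF2 * a + s.bF2);
  }
  for (int j = N - 1; j >= 0; --j) {
    acc = PB.col(j);
    for (int k = 1; k <= S; ++k)
      acc += s.WB1.cols(d + (k - 1) * H, d + k * H - 1) * C.HB.col(j + k);
    a = arma::tanh(acc);
    C.AB.col(j) = a;
    C.HB.col(j) = arma::tanh(s.WB2 * a + s.bB2);
  }
  // output net is fully batched
  mat ZP = s.WO1.cols(0, d - 1) * X
         + s.WO1.cols(d, d + H - 1) * C.HF.cols(S, S + N - 1)
         + s.WO1.cols(d + H, d + 2 * H - 1) * C.HB.cols(0, N - 1);
  ZP.each_col() += s.bO1;
  C.Z = arma::tanh(ZP);
  C.O = s.WO2 * C.Z;
  C.O.each_col() += s.bO2;
  softmax_cols(C.O);
}

struct StageGrad {
  mat WF1, WF2, WB1, WB2, WO1, WO2;
  vec bF1, bF2, bB1, bB2, bO1, bO2;
};

// dLogit (m x N) is dLoss/d(pre-softmax logits); fills parameter gradients
// and, when dX is non-null, dLoss/dX (d x N).
void stage_backward_core(const Stage& s, const mat& X, const StageCache& C,
                         const mat& dLogit, StageGrad& G, mat* dX) {
  const int N = X.n_cols, d = s.d, H = s.H, S = s.S;
  const mat HFwin = C.HF.cols(S, S + N - 1);
  const mat HBwin = C.HB.cols(0, N - 1);
  // output net (batched)
  G.WO2 = dLogit * C.Z.t();
  G.bO2 = arma::sum(dLogit, 1);
  mat dpreZ = (s.WO2.t() * dLogit) % (1.0 - arma::square(C.Z));
  G.WO1.set_size(s.K, d + 2 * H);
  G.WO1.cols(0, d - 1) = dpreZ * X.t();
  G.WO1.cols(d, d + H - 1) = dpreZ * HFwin.t();
  G.WO1.cols(d + H, d + 2 * H - 1) = dpreZ * HBwin.t();
  G.bO1 = arma::sum(dpreZ, 1);
  if (dX) *dX = s.WO1.cols(0, d - 1).t() * dpreZ;
  // state-chain adjoints, same padded layout as the caches
  mat dHF(H, N + S, arma::fill::zeros), dHB(H, N + S, arma::fill::zeros);
  dHF.cols(S, S + N - 1) = s.WO1.cols(d, d + H - 1).t() * dpreZ;
  dHB.cols(0, N - 1) = s.WO1.cols(d + H, d + 2 * H - 1).t() * dpreZ;
  mat DF(s.K, N), DFh(H, N), DB(s.K, N), DBh(H, N);
  vec g, da;
  for (int j = N - 1; j >= 0; --j) {
    g = dHF.col(S + j) % (1.0 - arma::square(C.HF.col(S + j)));
    DFh.col(j) = g;
    da = (s.WF2.t() * g) % (1.0 - arma::square(C.AF.col(j)));
    DF.col(j) = da;
    for (int k = 1; k <= S; ++k)  // adjoints into padding columns are inert
      dHF.col(S + j - k) +=
        s.WF1.cols(d + (k - 1) * H, d + k * H - 1).t() * da;
  }
  for (int j = 0; j < N; ++j) {
    g = dHB.col(j) % (1.0 - arma::square(C.HB.col(j)));
    DBh.col(j) = g;
    da = (s.WB2.t() * g) % (1.0 - arma::square(C.AB.col(j)));
    DB.col(j) = da;
    for (int k = 1; k <= S; ++k)
      if (j + k < N + S)
        dHB.col(j + k) +=
          s.WB1.cols(d + (k - 1) * H, d + k * H - 1).t() * da;
  }
  G.WF2 = DFh * C.AF.t();  G.bF2 = arma::sum(DFh, 1);
  G.WB2 = DBh * C.AB.t();  G.bB2 = arma::sum(DBh, 1);
  G.WF1.set_size(s.K, d + S * H);
  G.WB1.set_size(s.K, d + S * H);
  G.WF1.cols(0, d - 1) = DF * X.t();
  G.WB1.cols(0, d - 1) = DB * X.t();
  for (int k = 1; k <= S; ++k) {
    G.WF1.cols(d + (k - 1) * H, d + k * H - 1) =
      DF * C.HF.cols(S - k, S - k + N - 1).t();
    G.WB1.cols(d + (k - 1) * H, d + k * H - 1) =
      DB * C.HB.cols(k, k + N - 1).t();
  }
  G.bF1 = arma::sum(DF, 1);
  G.bB1 = arma::sum(DB, 1);
  if (dX) {
    *dX += s.WF1.cols(0, d - 1).t() * DF;
    *dX += s.WB1.cols(0, d - 1).t() * DB;
  }
}

// Filter between the stages: per position j the m first-stage outputs at j
// followed by 2p+1 window averages anchored at k_f = j + f(2w+1), f = -p..p.
// Out-of-range positions are dropped from each average's divisor.
mat filter_forward_core(const mat& C1, int w, int p) {
  const int m = C1.n_rows, N = C1.n_cols, win = 2 * w + 1;
  mat cum(m, N + 1, arma::fill::zeros);  // prefix sums over positions
  for (int j = 0; j < N; ++j) cum.col(j + 1) = cum.col(j) + C1.col(j);
  mat F(m * (2 * p + 2), N, arma::fill::zeros);
  for (int j = 0; j < N; ++j) {
    F.submat(0, j, m - 1, j) = C1.col(j);
    for (int f = -p; f <= p; ++f) {
      const int kf = j + f * win;
      const int lo = std::max(0, kf - w), hi = std::min(N - 1, kf + w);
      if (lo > hi) continue;
      const int row0 = m * (1 + f + p);
      F.submat(row0, j, row0 + m - 1, j) =
        (cum.col(hi + 1) - cum.col(lo)) / double(hi - lo + 1);
    }
  }
  return F;
}

// Adjoint of filter_forward_core: dF (m(2p+2) x N) -> dC1 (m x N).
mat filter_backward_core(const mat& dF, int m, int N, int w, int p) {
  const int win = 2 * w + 1;
  // difference trick: add g at lo, subtract at hi+1, prefix-sum at the end
  mat delta(m, N + 1, arma::fill::zeros);
  mat dC = dF.rows(0, m - 1);
  for (int j = 0; j < N; ++j) {
    for (int f = -p; f <= p; ++f) {
      const int kf = j + f * win;
      const int lo = std::max(0, kf - w), hi = std::min(N - 1, kf + w);
      if (lo > hi) continue;
      const int row0 = m * (1 + f + p);
      const vec g = dF.submat(row0, j, row0 + m - 1, j) / double(hi - lo + 1);
      delta.col(lo) += g;
      delta.col(hi + 1) -= g;
    }
  }
  vec run(m, arma::fill::zeros);
  for (int h = 0; h < N; ++h) {
    run += delta.col(h);
    dC.col(h) += run;
  }
  return dC;
}

List grad_to_list(const StageGrad& G) {
  return List::create(
    _["WF1"] = G.WF1, _["bF1"] = G.bF1, _["WF2"] = G.WF2, _["bF2"] = G.bF2,
    _["WB1"] = G.WB1, _["bB1"] = G.bB1, _["WB2"] = G.WB2, _["bB2"] = G.bB2,
    _["WO1"] = G.WO1, _["bO1"] = G.bO1, _["WO2"] = G.WO2, _["bO2"] = G.bO2);
}

double ce_sum(const mat& O, const IntegerVector& y) {
  double L = 0.0;
  for (int j = 0; j < (int)O.n_cols; ++j) {
    double pj = O(y[j], j);
    if (pj < 1e-12) pj = 1e-12;
    L -= std::log(pj);
  }
  return L;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_stage_forward(List stage, NumericMatrix X) {
  Stage s = stage_from_list(stage);
  mat Xt = arma::trans(as<mat>(X));
  if ((int)Xt.n_rows != s.d) stop("input width does not match stage width d");
  StageCache C;
  stage_forward_core(s, Xt, C);
  return wrap(arma::trans(C.O));
}

// [[Rcpp::export]]
NumericMatrix cpp_filter_inputs(NumericMatrix stage1_out, int w, int p) {
  mat C1 = arma::trans(as<mat>(stage1_out));
  return wrap(arma::trans(filter_forward_core(C1, w, p)));
}

// [[Rcpp::export]]
List cpp_two_stage_forward(List stage1, List stage2, int w, int p,
                           NumericMatrix X) {
  Stage s1 = stage_from_list(stage1), s2 = stage_from_list(stage2);
  mat Xt = arma::trans(as<mat>(X));
  StageCache C1, C2;
  stage_forward_core(s1, Xt, C1);
  mat F = filter_forward_core(C1.O, w, p);
  if ((int)F.n_rows != s2.d) stop("stage-2 input width != m*(2p+2)");
  stage_forward_core(s2, F, C2);
  return List::create(_["stage1"] = wrap(arma::trans(C1.O)),
                      _["output"] = wrap(arma::trans(C2.O)));
}

// Joint loss: sum over positions of cross-entropy at the stage-1 output plus
// cross-entropy at the stage-2 (final) output.  y holds 0-based class labels.
// [[Rcpp::export]]
List cpp_two_stage_grad(List stage1, List stage2, int w, int p,
                        NumericMatrix X, IntegerVector y) {
  Stage s1 = stage_from_list(stage1), s2 = stage_from_list(stage2);
  mat Xt = arma::trans(as<mat>(X));
  const int N = Xt.n_cols, m = s1.m;
  if ((int)y.size() != N) stop("label length != number of positions");
  StageCache C1, C2;
  stage_forward_core(s1, Xt, C1);
  mat F = filter_forward_core(C1.O, w, p);
  if ((int)F.n_rows != s2.d) stop("stage-2 input width != m*(2p+2)");
  stage_forward_core(s2, F, C2);

  mat Y(m, N, arma::fill::zeros);
  for (int j = 0; j < N; ++j) Y(y[j], j) = 1.0;

  // stage 2: d(sum CE)/d logits = O - Y; also need dLoss/d(filter inputs)
  StageGrad G2;
  mat dF;
  stage_backward_core(s2, F, C2, C2.O - Y, G2, &dF);
  mat dC1 = filter_backward_core(dF, m, N, w, p);

  // stage-1 logits: softmax Jacobian applied to dC1, plus its own CE term
  mat dLogit1(m, N);
  for (int j = 0; j < N; ++j) {
    const vec c = C1.O.col(j), g = dC1.col(j);
    dLogit1.col(j) = c % (g - arma::dot(g, c));
  }
  dLogit1 += C1.O - Y;
  StageGrad G1;
  stage_backward_core(s1, Xt, C1, dLogit1, G1, nullptr);

  const double l2 = ce_sum(C2.O, y), l1 = ce_sum(C1.O, y);
  return List::create(
    _["loss"] = l1 + l2, _["loss_final"] = l2, _["n"] = N,
    _["grad1"] = grad_to_list(G1), _["grad2"] = grad_to_list(G2),
    _["output"] = wrap(arma::trans(C2.O)),
    _["stage1"] = wrap(arma::trans(C1.O)));
}

// [[Rcpp::export]]
double cpp_two_stage_loss(List stage1, List stage2, int w, int p,
                          NumericMatrix X, IntegerVector y) {
  Stage s1 = stage_from_list(stage1), s2 = stage_from_list(stage2);
  mat Xt = arma::trans(as<mat>(X));
  StageCache C1, C2;
  stage_forward_core(s1, Xt, C1);
  mat F = filter_forward_core(C1.O, w, p);
  stage_forward_core(s2, F, C2);
  return ce_sum(C1.O, y) + ce_sum(C2.O, y);
}
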