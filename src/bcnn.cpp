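// Two-branch ("bifocal") convolutional network: im2col + GEMM convolutions.
//
// Activation layout: arma::mat with rows = channels and columns indexed by
// n*H*W + y*W + x (sample-major, then row-major pixels). All convolutions are
// 3x3, stride 1, zero-padded ("same"); each conv block is conv -> ReLU ->
// 2x2 max-pool. Each branch ends in global average pooling; branch vectors
// are concatenated (narrow first) and fed to a ReLU hidden layer and a
// 2-way softmax.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// The 9 neighbourhood offsets correspond to linear pixel-index shifts
// s = dy*W + dx, so each row block of the im2col matrix is one bulk shifted
// copy of the activation block per sample, followed by zeroing of the
// columns where the shift wrapped across an x-border.
static mat im2col3(const mat& A, int H, int W, int N) {
  const int C = A.n_rows;
  const size_t HW = (size_t)H * W;
  mat B(9 * C, HW * N, fill::zeros);
  int idx = 0;
  for (int dy = -1; dy <= 1; ++dy) {
    for (int dx = -1; dx <= 1; ++dx) {
      const int rb = idx * C;
      const long s = (long)dy * W + dx;
      const long p0 = std::max(0L, -s), p1 = (long)HW - 1 - std::max(0L, s);
      for (int n = 0; n < N; ++n) {
        const size_t base = (size_t)n * HW;
        B.submat(rb, base + p0, rb + C - 1, base + p1) =
          A.cols(base + p0 + s, base + p1 + s);
        if (dx != 0) {
          const int xbad = (dx < 0) ? 0 : W - 1;
          for (int y = 0; y < H; ++y) {
            const long p = (long)y * W + xbad;
            if (p < p0 || p > p1) continue;
            B.submat(rb, base + p, rb + C - 1, base + p).zeros();
          }
        }
      }
      ++idx;
    }
  }
  return B;
}

static mat col2im3(mat& dB, int H, int W, int N, int C) {
  const size_t HW = (size_t)H * W;
  mat dA(C, HW * N, fill::zeros);
  int idx = 0;
  for (int dy = -1; dy <= 1; ++dy) {
    for (int dx = -1; dx <= 1; ++dx) {
      const int rb = idx * C;
      const long s = (long)dy * W + dx;
      const long p0 = std::max(0L, -s), p1 = (long)HW - 1 - std::max(0L, s);
      for (int n = 0; n < N; ++n) {
        const size_t base = (size_t)n * HW;
        if (dx != 0) {  // drop contributions that would wrap across a border
          const int xbad = (dx < 0) ? 0 : W - 1;
          for (int y = 0; y < H; ++y) {
            const long p = (long)y * W + xbad;
            if (p < p0 || p > p1) continue;
            dB.submat(rb, base + p, rb + C - 1, base + p).zeros();
          }
        }
        dA.cols(base + p0 + s, base + p1 + s) +=
          dB.submat(rb, base + p0, rb + C - 1, base + p1);
      }
      ++idx;
    }
  }
  return dA;
}

static mat maxpool2(const mat& R, int H, int W, int N, umat& amax) {
  const int C = R.n_rows, Ho = H / 2, Wo = W / 2;
  const size_t oHW = (size_t)Ho * Wo;
  mat P(C, oHW * N);
  amax.set_size(C, oHW * N);
  for (int n = 0; n < N; ++n) {
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        const size_t oc = n * oHW + (size_t)oy * Wo + ox;
        const size_t c00 = (size_t)n * H * W + (size_t)(2 * oy) * W + 2 * ox;
        const size_t cand[4] = {c00, c00 + 1, c00 + W, c00 + W + 1};
        for (int c = 0; c < C; ++c) {
          double best = R(c, cand[0]);
          size_t bi = cand[0];
          for (int k = 1; k < 4; ++k)
            if (R(c, cand[k]) > best) { best = R(c, cand[k]); bi = cand[k]; }
          P(c, oc) = best;
          amax(c, oc) = bi;
        }
      }
    }
  }
  return P;
}

// R array (H, W, C, N), column-major -> (C x H*W*N) activation matrix
static mat arr_to_act(const Rcpp::NumericVector& arr) {
  Rcpp::IntegerVector d = arr.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = (d.size() > 3) ? d[3] : 1;
  const size_t HW = (size_t)H * W;
  mat A(C, HW * N);
  const double* p = arr.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y)
          A(c, n * HW + (size_t)y * W + x) =
            p[y + (size_t)H * x + HW * c + HW * C * n];
  return A;
}

struct BranchParams {
  mat W1, W2, W3;
  vec b1, b2, b3;
};

static BranchParams get_branch(const Rcpp::List& params, const std::string& pre) {
  BranchParams bp;
  bp.W1 = Rcpp::as<mat>(params[pre + "W1"]);
  bp.W2 = Rcpp::as<mat>(params[pre + "W2"]);
  bp.W3 = Rcpp::as<mat>(params[pre + "W3"]);
  bp.b1 = Rcpp::as<vec>(params[pre + "b1"]);
  bp.b2 = Rcpp::as<vec>(params[pre + "b2"]);
  bp.b3 = Rcpp::as<vec>(params[pre + "b3"]);
  return bp;
}

struct BranchCache {
  int H, W, N;
  mat B1, Z1, B2, Z2, B3, Z3;   // im2col inputs and pre-activation maps
  umat a1, a2, a3;              // max-pool argmax (source column per output)
  mat P1, P2, P3;               // pooled maps
  mat G;                        // global-average-pooled features (C3 x N)
};

static void branch_forward(const BranchParams& bp, const mat& A0,
                           int H, int W, int N, BranchCache& cc, bool keep) {
  cc.H = H; cc.W = W; cc.N = N;
  mat B1 = im2col3(A0, H, W, N);
  mat Z1 = bp.W1 * B1; Z1.each_col() += bp.b1;
  mat R1 = clamp(Z1, 0.0, datum::inf);
  umat a1; mat P1 = maxpool2(R1, H, W, N, a1);
  int H2 = H / 2, W2 = W / 2;

  mat B2 = im2col3(P1, H2, W2, N);
  mat Z2 = bp.W2 * B2; Z2.each_col() += bp.b2;
  mat R2 = clamp(Z2, 0.0, datum::inf);
  umat a2; mat P2 = maxpool2(R2, H2, W2, N, a2);
  int H3 = H2 / 2, W3 = W2 / 2;

  mat B3 = im2col3(P2, H3, W3, N);
  mat Z3 = bp.W3 * B3; Z3.each_col() += bp.b3;
  mat R3 = clamp(Z3, 0.0, datum::inf);
  umat a3; mat P3 = maxpool2(R3, H3, W3, N, a3);
  int H4 = H3 / 2, W4 = W3 / 2;

  const size_t oHW = (size_t)H4 * W4;
  mat G(P3.n_rows, N);
  for (int n = 0; n < N; ++n)
    G.col(n) = mean(P3.cols(n * oHW, (n + 1) * oHW - 1), 1);

  cc.G = G;
  if (keep) {
    cc.B1 = std::move(B1); cc.Z1 = std::move(Z1); cc.a1 = std::move(a1);
    cc.P1 = std::move(P1);
    cc.B2 = std::move(B2); cc.Z2 = std::move(Z2); cc.a2 = std::move(a2);
    cc.P2 = std::move(P2);
    cc.B3 = std::move(B3); cc.Z3 = std::move(Z3); cc.a3 = std::move(a3);
    cc.P3 = std::move(P3);
  }
}

// Backward through one branch from dG (C3 x N); fills gradient mats.
static void branch_backward(const BranchParams& bp, const BranchCache& cc,
                            const mat& dG,
                            mat& dW1, vec& db1, mat& dW2, vec& db2,
                            mat& dW3, vec& db3) {
  const int H = cc.H, W = cc.W, N = cc.N;
  const int H2 = H / 2, W2 = W / 2, H3 = H2 / 2, W3 = W2 / 2;
  const int H4 = H3 / 2, W4 = W3 / 2;
  const size_t oHW = (size_t)H4 * W4;

  mat dP3(dG.n_rows, oHW * N);
  for (int n = 0; n < N; ++n)
    dP3.cols(n * oHW, (n + 1) * oHW - 1) =
      repmat(dG.col(n) / (double)oHW, 1, oHW);

  mat dR3(cc.Z3.n_rows, cc.Z3.n_cols, fill::zeros);
  for (size_t j = 0; j < dP3.n_cols; ++j)
    for (size_t c = 0; c < dP3.n_rows; ++c)
      dR3(c, cc.a3(c, j)) += dP3(c, j);
  mat dZ3 = dR3 % conv_to<mat>::from(cc.Z3 > 0.0);
  dW3 = dZ3 * cc.B3.t();
  db3 = sum(dZ3, 1);
  mat dB3 = bp.W3.t() * dZ3;
  mat dP2 = col2im3(dB3, H3, W3, N, cc.P2.n_rows);

  mat dR2(cc.Z2.n_rows, cc.Z2.n_cols, fill::zeros);
  for (size_t j = 0; j < dP2.n_cols; ++j)
    for (size_t c = 0; c < dP2.n_rows; ++c)
      dR2(c, cc.a2(c, j)) += dP2(c, j);
  mat dZ2 = dR2 % conv_to<mat>::from(cc.Z2 > 0.0);
  dW2 = dZ2 * cc.B2.t();
  db2 = sum(dZ2, 1);
  mat dB2 = bp.W2.t() * dZ2;
  mat dP1 = col2im3(dB2, H2, W2, N, cc.P1.n_rows);

  mat dR1(cc.Z1.n_rows, cc.Z1.n_cols, fill::zeros);
  for (size_t j = 0; j < dP1.n_cols; ++j)
    for (size_t c = 0; c < dP1.n_rows; ++c)
      dR1(c, cc.a1(c, j)) += dP1(c, j);
  mat dZ1 = dR1 % conv_to<mat>::from(cc.Z1 > 0.0);
  dW1 = dZ1 * cc.B1.t();
  db1 = sum(dZ1, 1);
}

static mat softmax_cols(const mat& L) {
  mat P = L;
  P.each_row() -= max(P, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

// Forward pass: class probabilities, one row per pair (columns: neg, pos).
// [[Rcpp::export]]
Rcpp::NumericMatrix bcnn_forward_cpp(Rcpp::List params,
                                     Rcpp::NumericVector narrow,
                                     Rcpp::NumericVector wide) {
  Rcpp::IntegerVector dn = narrow.attr("dim");
  Rcpp::IntegerVector dw = wide.attr("dim");
  const int N = (dn.size() > 3) ? dn[3] : 1;
  BranchParams bn = get_branch(params, "n"), bw = get_branch(params, "w");
  mat An = arr_to_act(narrow), Aw = arr_to_act(wide);
  BranchCache cn, cw;
  branch_forward(bn, An, dn[0], dn[1], N, cn, false);
  branch_forward(bw, Aw, dw[0], dw[1], N, cw, false);
  mat F = join_cols(cn.G, cw.G);
  mat Wh = Rcpp::as<mat>(params["Wh"]); vec bh = Rcpp::as<vec>(params["bh"]);
  mat Wo = Rcpp::as<mat>(params["Wo"]); vec bo = Rcpp::as<vec>(params["bo"]);
  mat Zh = Wh * F; Zh.each_col() += bh;
  mat Hh = clamp(Zh, 0.0, datum::inf);
  mat L = Wo * Hh; L.each_col() += bo;
  mat P = softmax_cols(L);
  return Rcpp::wrap(mat(P.t()));
}

// Mean cross-entropy loss + gradients for all parameters.
// y: integer class per pair, 0 = negative, 1 = positive.
// [[Rcpp::export]]
Rcpp::List bcnn_grad_cpp(Rcpp::List params,
                         Rcpp::NumericVector narrow,
                         Rcpp::NumericVector wide,
                         Rcpp::IntegerVector y) {
  Rcpp::IntegerVector dn = narrow.attr("dim");
  Rcpp::IntegerVector dw = wide.attr("dim");
  const int N = (dn.size() > 3) ? dn[3] : 1;
  BranchParams bn = get_branch(params, "n"), bw = get_branch(params, "w");
  mat An = arr_to_act(narrow), Aw = arr_to_act(wide);
  BranchCache cn, cw;
  branch_forward(bn, An, dn[0], dn[1], N, cn, true);
  branch_forward(bw, Aw, dw[0], dw[1], N, cw, true);
  mat F = join_cols(cn.G, cw.G);

  mat Wh = Rcpp::as<mat>(params["Wh"]); vec bh = Rcpp::as<vec>(params["bh"]);
  mat Wo = Rcpp::as<mat>(params["Wo"]); vec bo = Rcpp::as<vec>(params["bo"]);
  mat Zh = Wh * F; Zh.each_col() += bh;
  mat Hh = clamp(Zh, 0.0, datum::inf);
  mat L = Wo * Hh; L.each_col() += bo;
  mat P = softmax_cols(L);

  double loss = 0.0;
  mat dL = P;
  for (int n = 0; n < N; ++n) {
    const int cls = y[n];
    loss -= std::log(std::max(P(cls, n), 1e-12));
    dL(cls, n) -= 1.0;
  }
  loss /= N;
  dL /= (double)N;

  mat dWo = dL * Hh.t();
  vec dbo = sum(dL, 1);
  mat dHh = Wo.t() * dL;
  mat dZh = dHh % conv_to<mat>::from(Zh > 0.0);
  mat dWh = dZh * F.t();
  vec dbh = sum(dZh, 1);
  mat dF = Wh.t() * dZh;

  const int c3 = cn.G.n_rows;
  mat dGn = dF.rows(0, c3 - 1);
  mat dGw = dF.rows(c3, dF.n_rows - 1);

  mat ndW1, ndW2, ndW3, wdW1, wdW2, wdW3;
  vec ndb1, ndb2, ndb3, wdb1, wdb2, wdb3;
  branch_backward(bn, cn, dGn, ndW1, ndb1, ndW2, ndb2, ndW3, ndb3);
  branch_backward(bw, cw, dGw, wdW1, wdb1, wdW2, wdb2, wdW3, wdb3);

  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("nW1") = ndW1, Rcpp::Named("nb1") = ndb1,
    Rcpp::Named("nW2") = ndW2, Rcpp::Named("nb2") = ndb2,
    Rcpp::Named("nW3") = ndW3, Rcpp::Named("nb3") = ndb3,
    Rcpp::Named("wW1") = wdW1, Rcpp::Named("wb1") = wdb1,
    Rcpp::Named("wW2") = wdW2, Rcpp::Named("wb2") = wdb2,
    Rcpp::Named("wW3") = wdW3, Rcpp::Named("wb3") = wdb3,
    Rcpp::Named("Wh") = dWh, Rcpp::Named("bh") = dbh,
    Rcpp::Named("Wo") = dWo, Rcpp::Named("bo") = dbo);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("probs") = Rcpp::wrap(mat(P.t())),
                            Rcpp::Named("grads") = grads);
}
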