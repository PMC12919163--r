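// Stacked bidirectional LSTM for fixed-length EEG segments: forward pass,
// full backpropagation through time, and binary cross-entropy head. The ADAM
// loop, batching and early stopping live on the R side; this file only
// computes loss/gradients for one mini-batch (or predictions). The batch is
// processed jointly: at each timestep the gate pre-activations of all
// sequences are one matrix product, which is what makes single-CPU training
// practical at these problem sizes.
//
// Parameter list layout (names fixed, shared with R):
//   W1f (4H x F)  U1f (4H x H)  b1f (4H)   layer-1 forward direction
//   W1b, U1b, b1b                          layer-1 backward direction
//   W2f (4H x 2H) U2f (4H x H)  b2f        layer-2 forward direction
//   W2b, U2b, b2b                          layer-2 backward direction
//   w_out (2H)    b_out (scalar)           sigmoid head on the concatenated
//                                          final hidden states of layer 2
// Gate row blocks within 4H: input, forget, candidate, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// Per-timestep caches for one direction; every entry is H x B.
struct Cache {
  std::vector<mat> I, F, G, O, C, TC, H;
  void init(uword T) {
    I.resize(T); F.resize(T); G.resize(T); O.resize(T);
    C.resize(T); TC.resize(T); H.resize(T);
  }
};

// Run one LSTM direction over a batched sequence X[t] (F_in x B each).
void lstm_forward(const std::vector<mat>& X, const mat& W, const mat& U,
                  const vec& b, Cache& cc) {
  const uword T = X.size(), Hn = U.n_cols, B = X[0].n_cols;
  cc.init(T);
  mat h(Hn, B, fill::zeros), c(Hn, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = W * X[t] + U * h;
    A.each_col() += b;
    mat gi = 1.0 / (1.0 + exp(-A.rows(0, Hn - 1)));
    mat gf = 1.0 / (1.0 + exp(-A.rows(Hn, 2 * Hn - 1)));
    mat gg = tanh(A.rows(2 * Hn, 3 * Hn - 1));
    mat go = 1.0 / (1.0 + exp(-A.rows(3 * Hn, 4 * Hn - 1)));
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    cc.I[t] = std::move(gi); cc.F[t] = std::move(gf);
    cc.G[t] = std::move(gg); cc.O[t] = std::move(go);
    cc.C[t] = c; cc.TC[t] = std::move(tc); cc.H[t] = h;
  }
}

// BPTT for one direction. dH[t] is the upstream gradient on the hidden
// outputs (H x B). Accumulates into dW/dU/db (callers zero them once per
// batch); writes input gradients into dX[t] (F_in x B) when dX non-null.
void lstm_backward(const std::vector<mat>& X, const mat& W, const mat& U,
                   const Cache& cc, const std::vector<mat>& dH,
                   mat& dW, mat& dU, vec& db, std::vector<mat>* dX) {
  const uword T = X.size(), Hn = U.n_cols, B = X[0].n_cols;
  if (dX) dX->resize(T);
  mat dh_next(Hn, B, fill::zeros), dc_next(Hn, B, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    mat dh = dH[tt] + dh_next;
    const mat& gi = cc.I[tt]; const mat& gf = cc.F[tt];
    const mat& gg = cc.G[tt]; const mat& go = cc.O[tt];
    const mat& tc = cc.TC[tt];
    mat dgo = dh % tc;
    mat dc = dh % go % (1.0 - tc % tc) + dc_next;
    dc_next = dc % gf;
    mat da(4 * Hn, B);
    da.rows(0, Hn - 1) = (dc % gg) % gi % (1.0 - gi);
    da.rows(Hn, 2 * Hn - 1) = (tt == 0)
        ? mat(Hn, B, fill::zeros)
        : mat((dc % cc.C[tt - 1]) % gf % (1.0 - gf));
    da.rows(2 * Hn, 3 * Hn - 1) = (dc % gi) % (1.0 - gg % gg);
    da.rows(3 * Hn, 4 * Hn - 1) = dgo % go % (1.0 - go);
    dW += da * X[tt].t();
    if (tt > 0) dU += da * cc.H[tt - 1].t();
    db += sum(da, 1);
    if (dX) (*dX)[tt] = W.t() * da;
    dh_next = U.t() * da;
  }
}

struct Params {
  mat W1f, U1f, W1b, U1b, W2f, U2f, W2b, U2b;
  vec b1f, b1b, b2f, b2b, w_out;
  double b_out;
};

Params unpack(const Rcpp::List& p) {
  Params q;
  q.W1f = Rcpp::as<mat>(p["W1f"]); q.U1f = Rcpp::as<mat>(p["U1f"]);
  q.b1f = Rcpp::as<vec>(p["b1f"]);
  q.W1b = Rcpp::as<mat>(p["W1b"]); q.U1b = Rcpp::as<mat>(p["U1b"]);
  q.b1b = Rcpp::as<vec>(p["b1b"]);
  q.W2f = Rcpp::as<mat>(p["W2f"]); q.U2f = Rcpp::as<mat>(p["U2f"]);
  q.b2f = Rcpp::as<vec>(p["b2f"]);
  q.W2b = Rcpp::as<mat>(p["W2b"]); q.U2b = Rcpp::as<mat>(p["U2b"]);
  q.b2b = Rcpp::as<vec>(p["b2b"]);
  q.w_out = Rcpp::as<vec>(p["w_out"]);
  q.b_out = Rcpp::as<double>(p["b_out"]);
  return q;
}

}  // namespace

// Loss (weighted mean binary cross-entropy), per-sequence probabilities and,
// when want_grad, gradients for one mini-batch. X is a list of T x F matrices
// (one per sequence, equal T), y the 0/1 labels, w per-example loss weights
// (all 1 for the unweighted fit). Dropout uses inverted scaling and a
// dedicated mt19937 stream seeded from R so runs are reproducible.
// [[Rcpp::export]]
Rcpp::List cpp_bilstm_batch(Rcpp::List X, Rcpp::NumericVector y,
                            Rcpp::NumericVector w, Rcpp::List params,
                            double dropout, bool training, int seed,
                            bool want_grad) {
  Params P = unpack(params);
  const uword B = X.size();
  const uword Hn = P.U1f.n_cols;
  const double keep = 1.0 - dropout;
  const bool use_drop = training && dropout > 0.0;
  std::mt19937 gen(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // Gather the batch into per-timestep matrices (F x B).
  mat X0 = Rcpp::as<mat>(X[0]);
  const uword T = X0.n_rows, Fn = X0.n_cols;
  std::vector<mat> Xt(T, mat(Fn, B));
  for (uword s = 0; s < B; ++s) {
    mat Xs = Rcpp::as<mat>(X[s]);
    if (Xs.n_rows != T || Xs.n_cols != Fn)
      Rcpp::stop("all sequences must share the same length and width");
    for (uword t = 0; t < T; ++t) Xt[t].col(s) = Xs.row(t).t();
  }
  std::vector<mat> Xt_rev(T);
  for (uword t = 0; t < T; ++t) Xt_rev[t] = Xt[T - 1 - t];

  // Layer 1, both directions.
  Cache c1f, c1b;
  lstm_forward(Xt, P.W1f, P.U1f, P.b1f, c1f);
  lstm_forward(Xt_rev, P.W1b, P.U1b, P.b1b, c1b);

  // Layer-1 output at step t = [h_fwd(t); h_bwd(t)] (2H x B), with dropout.
  std::vector<mat> D1(T), mask1;
  if (use_drop) mask1.resize(T);
  for (uword t = 0; t < T; ++t) {
    D1[t] = join_cols(c1f.H[t], c1b.H[T - 1 - t]);
    if (use_drop) {
      mat m(2 * Hn, B);
      for (uword i = 0; i < m.n_elem; ++i)
        m(i) = unif(gen) < keep ? 1.0 / keep : 0.0;
      D1[t] %= m;
      mask1[t] = std::move(m);
    }
  }
  std::vector<mat> D1_rev(T);
  for (uword t = 0; t < T; ++t) D1_rev[t] = D1[T - 1 - t];

  // Layer 2, both directions.
  Cache c2f, c2b;
  lstm_forward(D1, P.W2f, P.U2f, P.b2f, c2f);
  lstm_forward(D1_rev, P.W2b, P.U2b, P.b2b, c2b);

  // Head on concatenated final hidden states V = [h2f(T); h2b(T)] (2H x B).
  mat V = join_cols(c2f.H[T - 1], c2b.H[T - 1]);
  mat maskv;
  if (use_drop) {
    maskv.set_size(2 * Hn, B);
    for (uword i = 0; i < maskv.n_elem; ++i)
      maskv(i) = unif(gen) < keep ? 1.0 / keep : 0.0;
    V %= maskv;
  }
  rowvec logits = P.w_out.t() * V + P.b_out;
  rowvec pr = 1.0 / (1.0 + exp(-logits));
  double loss = 0.0;
  Rcpp::NumericVector probs(B);
  for (uword s = 0; s < B; ++s) {
    probs[s] = pr(s);
    double pc = std::min(std::max(pr(s), 1e-12), 1.0 - 1e-12);
    loss += -w[s] * (y[s] * std::log(pc) +
                     (1.0 - y[s]) * std::log(1.0 - pc));
  }
  loss /= static_cast<double>(B);

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss,
                                      Rcpp::Named("probs") = probs);
  if (!want_grad) return out;

  mat dW1f(size(P.W1f), fill::zeros), dU1f(size(P.U1f), fill::zeros);
  mat dW1b(size(P.W1b), fill::zeros), dU1b(size(P.U1b), fill::zeros);
  mat dW2f(size(P.W2f), fill::zeros), dU2f(size(P.U2f), fill::zeros);
  mat dW2b(size(P.W2b), fill::zeros), dU2b(size(P.U2b), fill::zeros);
  vec db1f(4 * Hn, fill::zeros), db1b(4 * Hn, fill::zeros);
  vec db2f(4 * Hn, fill::zeros), db2b(4 * Hn, fill::zeros);

  rowvec dlogit(B);
  for (uword s = 0; s < B; ++s)
    dlogit(s) = w[s] * (pr(s) - y[s]) / static_cast<double>(B);
  vec dw_out = V * dlogit.t();
  double db_out = accu(dlogit);
  mat dV = P.w_out * dlogit;  // 2H x B
  if (use_drop) dV %= maskv;

  std::vector<mat> zH(T, mat(Hn, B, fill::zeros));
  std::vector<mat> dH2f = zH, dH2b = zH;
  dH2f[T - 1] = dV.rows(0, Hn - 1);
  dH2b[T - 1] = dV.rows(Hn, 2 * Hn - 1);

  std::vector<mat> dXf, dXb_r;
  lstm_backward(D1, P.W2f, P.U2f, c2f, dH2f, dW2f, dU2f, db2f, &dXf);
  lstm_backward(D1_rev, P.W2b, P.U2b, c2b, dH2b, dW2b, dU2b, db2b, &dXb_r);

  std::vector<mat> dH1f(T), dH1b(T);
  for (uword t = 0; t < T; ++t) {
    mat dD1 = dXf[t] + dXb_r[T - 1 - t];
    if (use_drop) dD1 %= mask1[t];
    dH1f[t] = dD1.rows(0, Hn - 1);
    dH1b[T - 1 - t] = dD1.rows(Hn, 2 * Hn - 1);
  }
  lstm_backward(Xt, P.W1f, P.U1f, c1f, dH1f, dW1f, dU1f, db1f, nullptr);
  lstm_backward(Xt_rev, P.W1b, P.U1b, c1b, dH1b, dW1b, dU1b, db1b, nullptr);

  out["grads"] = Rcpp::List::create(
      Rcpp::Named("W1f") = dW1f, Rcpp::Named("U1f") = dU1f,
      Rcpp::Named("b1f") = db1f, Rcpp::Named("W1b") = dW1b,
      Rcpp::Named("U1b") = dU1b, Rcpp::Named("b1b") = db1b,
      Rcpp::Named("W2f") = dW2f, Rcpp::Named("U2f") = dU2f,
      Rcpp::Named("b2f") = db2f, Rcpp::Named("W2b") = dW2b,
      Rcpp::Named("U2b") = dU2b, Rcpp::Named("b2b") = db2b,
      Rcpp::Named("w_out") = dw_out, Rcpp::Named("b_out") = db_out);
  return out;
}

// Per-sample median over rows, for each column (the common median reference).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_col_median(Rcpp::NumericMatrix m) {
  mat X = Rcpp::as<mat>(m);
  rowvec med = median(X, 0);
  return Rcpp::wrap(conv_to<std::vector<double>>::from(med));
}
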