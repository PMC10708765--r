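// Hot loops of the model zoo: batched LSTM recurrence and additive attention
// pooling, with exact analytic backward passes. Shapes follow Armadillo cube
// conventions: a batch of sequences is (batch, feature, time).
//
// Gate column layout in the 4H-wide pre-activation z: [i | f | g | o]
// with i, f, o sigmoid and g tanh; c_t = f*c_{t-1} + i*g, h_t = o*tanh(c_t).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b) {
  const uword B = X.n_rows, T = X.n_slices, H = Wh.n_rows;
  cube Hs(B, H, T), Cs(B, H, T), G(B, 4 * H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat z = X.slice(t) * Wx + h * Wh;
    z.each_row() += br;
    mat i = sigm(z.cols(0, H - 1));
    mat f = sigm(z.cols(H, 2 * H - 1));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = sigm(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    G.slice(t) = join_rows(join_rows(i, f), join_rows(g, o));
    Cs.slice(t) = c;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs,
                            Rcpp::Named("G") = G);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
Rcpp::List lstm_backward_cpp(const arma::cube& dH, const arma::cube& X,
                             const arma::cube& Hs, const arma::cube& Cs,
                             const arma::cube& G, const arma::mat& Wx,
                             const arma::mat& Wh) {
  const uword B = X.n_rows, T = X.n_slices, H = Wh.n_rows;
  cube dX(B, X.n_cols, T, fill::zeros);
  mat dWx(Wx.n_rows, Wx.n_cols, fill::zeros);
  mat dWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    mat i = G.slice(tt).cols(0, H - 1);
    mat f = G.slice(tt).cols(H, 2 * H - 1);
    mat g = G.slice(tt).cols(2 * H, 3 * H - 1);
    mat o = G.slice(tt).cols(3 * H, 4 * H - 1);
    mat tc = tanh(Cs.slice(tt));
    mat dh = dH.slice(tt) + dh_next;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat c_prev = (tt > 0) ? Cs.slice(tt - 1) : mat(B, H, fill::zeros);
    mat dzi = (dc % g) % i % (1.0 - i);
    mat dzf = (dc % c_prev) % f % (1.0 - f);
    mat dzg = (dc % i) % (1.0 - g % g);
    mat dzo = (dh % tc) % o % (1.0 - o);
    mat dz = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));
    mat h_prev = (tt > 0) ? Hs.slice(tt - 1) : mat(B, H, fill::zeros);
    dWx += X.slice(tt).t() * dz;
    dWh += h_prev.t() * dz;
    db += sum(dz, 0);
    dX.slice(tt) = dz * Wx.t();
    dh_next = dz * Wh.t();
    dc_next = dc % f;
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
      Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db.t());
}

// Additive (tanh-scored) attention over the time axis of a (B, D, T) cube:
//   u_t = tanh(H_t W + b), s[, t] = u_t v, w = softmax_rows(s),
//   ctx = sum_t w[, t] * H_t.
// [[Rcpp::export(name = ".attn_forward_cpp")]]
Rcpp::List attn_forward_cpp(const arma::cube& Hc, const arma::mat& W,
                            const arma::vec& b, const arma::vec& v) {
  const uword B = Hc.n_rows, D = Hc.n_cols, T = Hc.n_slices, A = W.n_cols;
  cube U(B, A, T);
  mat s(B, T);
  rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat u = Hc.slice(t) * W;
    u.each_row() += br;
    u = tanh(u);
    U.slice(t) = u;
    s.col(t) = u * v;
  }
  mat w = exp(s.each_col() - max(s, 1));
  w.each_col() /= sum(w, 1);
  mat ctx(B, D, fill::zeros);
  for (uword t = 0; t < T; ++t) ctx += Hc.slice(t).each_col() % w.col(t);
  return Rcpp::List::create(Rcpp::Named("ctx") = ctx, Rcpp::Named("wgt") = w,
                            Rcpp::Named("U") = U);
}

// [[Rcpp::export(name = ".attn_backward_cpp")]]
Rcpp::List attn_backward_cpp(const arma::mat& dctx, const arma::cube& Hc,
                             const arma::cube& U, const arma::mat& wgt,
                             const arma::mat& W, const arma::vec& v) {
  const uword B = Hc.n_rows, T = Hc.n_slices;
  mat dwgt(B, T);
  for (uword t = 0; t < T; ++t)
    dwgt.col(t) = sum(dctx % Hc.slice(t), 1);
  vec dot = sum(wgt % dwgt, 1);
  mat ds = wgt % (dwgt.each_col() - dot);
  cube dHc(size(Hc), fill::zeros);
  mat dW(size(W), fill::zeros);
  rowvec db(W.n_cols, fill::zeros);
  vec dv(v.n_elem, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    dHc.slice(t) = dctx.each_col() % wgt.col(t);
    mat du = (ds.col(t) * v.t()) % (1.0 - U.slice(t) % U.slice(t));
    dv += U.slice(t).t() * ds.col(t);
    dW += Hc.slice(t).t() * du;
    db += sum(du, 0);
    dHc.slice(t) += du * W.t();
  }
  return Rcpp::List::create(Rcpp::Named("dH") = dHc, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db.t(),
                            Rcpp::Named("dv") = dv);
}
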