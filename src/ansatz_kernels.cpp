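// Batched forward/backward kernels for the amplitude networks.
// Layout conventions (shared with R/ansatz.R):
//   occupations N: L x B integer matrix, one configuration per column
//   W0: Nhid x L, b0: Nhid, W1: R x Nhid, b1: R
//   MBF output head: R = L * Nmodal, row r = i*Nmodal + k encodes modal
//   coefficient (mode i, basis index k), both 0-based here.
//   FNN head: R = 1, amplitude = tanh(z1).
//   Parameter vector: [vec(W0); b0; vec(W1); b1; (vec(phi0))], column-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat forward_hidden(const mat& W0, const vec& b0, const imat& N) {
  mat X = conv_to<mat>::from(N);
  mat H = W0 * X;
  H.each_col() += b0;
  return tanh(H);
}

// [[Rcpp::export]]
arma::vec cpp_amp_mbf(const arma::mat& W0, const arma::vec& b0,
                      const arma::mat& W1, const arma::vec& b1,
                      const arma::mat& phi0, const arma::imat& N) {
  const uword L = phi0.n_rows, Nmodal = phi0.n_cols, B = N.n_cols;
  mat H = forward_hidden(W0, b0, N);
  mat O = W1 * H;
  O.each_col() += b1;
  O = tanh(O);
  vec amp(B);
  for (uword b = 0; b < B; ++b) {
    double a = 1.0;
    for (uword i = 0; i < L; ++i) {
      uword k = (uword)N(i, b);
      a *= phi0(i, k) + O(i * Nmodal + k, b);
    }
    amp(b) = a;
  }
  return amp;
}

// [[Rcpp::export]]
arma::vec cpp_amp_fnn(const arma::mat& W0, const arma::vec& b0,
                      const arma::mat& W1, const arma::vec& b1,
                      const arma::imat& N) {
  mat H = forward_hidden(W0, b0, N);
  mat O = W1 * H;
  O.each_col() += b1;
  return vectorise(tanh(O));
}

// Returns list(amp, D) with D a B x P matrix of d log|Psi| / d theta.
// train_weights = false freezes the network blocks (VSCF mode);
// train_phi0 appends derivatives w.r.t. the fixed modal matrix.
// [[Rcpp::export]]
Rcpp::List cpp_grad_mbf(const arma::mat& W0, const arma::vec& b0,
                        const arma::mat& W1, const arma::vec& b1,
                        const arma::mat& phi0, const arma::imat& N,
                        bool train_weights, bool train_phi0) {
  const uword L = phi0.n_rows, Nmodal = phi0.n_cols, B = N.n_cols;
  const uword Nhid = W0.n_rows, R = W1.n_rows;
  mat X = conv_to<mat>::from(N);
  mat H = forward_hidden(W0, b0, N);
  mat O = W1 * H;
  O.each_col() += b1;
  O = tanh(O);

  uword nw = Nhid * L + Nhid + R * Nhid + R;
  uword P = (train_weights ? nw : 0) + (train_phi0 ? L * Nmodal : 0);
  mat D(B, P, fill::zeros);
  vec amp(B);

  vec s(R), dz1(R), dh(Nhid), dz0(Nhid);
  for (uword b = 0; b < B; ++b) {
    double a = 1.0;
    s.zeros();
    for (uword i = 0; i < L; ++i) {
      uword k = (uword)N(i, b);
      double phi = phi0(i, k) + O(i * Nmodal + k, b);
      a *= phi;
      s(i * Nmodal + k) = 1.0 / phi;  // d log|Psi| / d phi_i,k(n)
    }
    amp(b) = a;
    uword off = 0;
    if (train_weights) {
      dz1 = s % (1.0 - square(O.col(b)));
      dh = W1.t() * dz1;
      dz0 = dh % (1.0 - square(H.col(b)));
      // W0 block (col-major), then b0, W1, b1
      for (uword j = 0; j < L; ++j)
        for (uword q = 0; q < Nhid; ++q)
          D(b, off + j * Nhid + q) = dz0(q) * X(j, b);
      off += Nhid * L;
      for (uword q = 0; q < Nhid; ++q) D(b, off + q) = dz0(q);
      off += Nhid;
      for (uword q = 0; q < Nhid; ++q)
        for (uword r = 0; r < R; ++r)
          D(b, off + q * R + r) = dz1(r) * H(q, b);
      off += R * Nhid;
      for (uword r = 0; r < R; ++r) D(b, off + r) = dz1(r);
      off += R;
    }
    if (train_phi0) {
      for (uword i = 0; i < L; ++i) {
        uword k = (uword)N(i, b);
        D(b, off + k * L + i) = s(i * Nmodal + k);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("amp") = amp, Rcpp::Named("D") = D);
}

// [[Rcpp::export]]
Rcpp::List cpp_grad_fnn(const arma::mat& W0, const arma::vec& b0,
                        const arma::mat& W1, const arma::vec& b1,
                        const arma::imat& N) {
  const uword L = N.n_rows, B = N.n_cols, Nhid = W0.n_rows;
  mat X = conv_to<mat>::from(N);
  mat H = forward_hidden(W0, b0, N);
  rowvec z = W1.row(0) * H + b1(0);
  rowvec psi = tanh(z);
  uword P = Nhid * L + Nhid + Nhid + 1;
  mat D(B, P, fill::zeros);
  vec dh(Nhid), dz0(Nhid);
  for (uword b = 0; b < B; ++b) {
    double dlog = (1.0 - psi(b) * psi(b)) / psi(b);
    dh = W1.t() * dlog;
    dz0 = dh % (1.0 - square(H.col(b)));
    uword off = 0;
    for (uword j = 0; j < L; ++j)
      for (uword q = 0; q < Nhid; ++q)
        D(b, off + j * Nhid + q) = dz0(q) * X(j, b);
    off += Nhid * L;
    for (uword q = 0; q < Nhid; ++q) D(b, off + q) = dz0(q);
    off += Nhid;
    for (uword q = 0; q < Nhid; ++q) D(b, off + q) = dlog * H(q, b);
    off += Nhid;
    D(b, off) = dlog;
  }
  return Rcpp::List::create(Rcpp::Named("amp") = conv_to<vec>::from(psi.t()),
                            Rcpp::Named("D") = D);
}
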