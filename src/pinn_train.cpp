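// Full-batch Adam training loop for the SIR physics-informed network.
//
// The network maps time t to the three compartment proportions through
// dense ReLU layers. The composite loss is
//   L = sum_c w_ode[c] * mean_j r_c(t_j)^2
//     + sum_c w_ic[c]  * (u_c(t_0) - uhat_c(t_0))^2
//     + sum_c w_data[c]/n * sum_j (u_c(t_j) - uhat_c(t_j))^2
// with residuals
//   r_S = dS/dt + beta*S*I/N,  r_I = dI/dt - beta*S*I/N + sigma*I,
//   r_R = dR/dt - sigma*I    (N = 1 on the normalized scale used here).
//
// d(uhat)/dt is the exact forward-mode tangent through the ReLU activation
// pattern; its parameter gradient treats the activation masks as constant,
// matching the reverse-mode autodiff convention (relu' derivative 0 a.e.).
// beta and sigma are appended to the learnable set and take identical Adam
// steps unless frozen. No RNG is used here: initialization happens in R,
// so the loop is deterministic given its inputs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct LossParts {
  double ode_S, ode_I, ode_R, ic, data, total;
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_pinn(Rcpp::List W0, Rcpp::List b0, arma::vec t,
                          arma::mat U, arma::vec lambda0, double lr,
                          int iterations, int trace_every, arma::vec w_ode,
                          arma::vec w_ic, arma::vec w_data,
                          bool freeze_lambda) {
  const int L = W0.size();
  const arma::uword n = t.n_elem;
  if (U.n_rows != 3 || U.n_cols != n)
    Rcpp::stop("U must be a 3 x length(t) matrix");

  std::vector<mat> W(L), mW(L), vW(L), gW(L);
  std::vector<vec> b(L), mb(L), vb(L), gb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W0[l]);
    b[l] = Rcpp::as<vec>(b0[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }
  vec lambda = lambda0;  // (beta, sigma)
  vec ml(2, arma::fill::zeros), vl(2, arma::fill::zeros);

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  // forward storage: A[l] is the input activation of layer l (A[0] = t'),
  // V[l] the matching tangent d(A[l])/dt, mask[l] the ReLU pattern of
  // hidden layer l.
  std::vector<mat> A(L + 1), V(L + 1);
  std::vector<arma::umat> mask(L - 1);
  A[0] = arma::conv_to<rowvec>::from(t);
  V[0] = rowvec(n, arma::fill::ones);

  mat Uhat, D;
  auto forward = [&]() {
    for (int l = 0; l < L - 1; ++l) {
      mat Z = W[l] * A[l];
      Z.each_col() += b[l];
      mask[l] = Z > 0;
      A[l + 1] = Z % mask[l];
      V[l + 1] = (W[l] * V[l]) % mask[l];
    }
    Uhat = W[L - 1] * A[L - 1];
    Uhat.each_col() += b[L - 1];
    D = W[L - 1] * V[L - 1];
  };

  rowvec rS, rI, rR;
  auto loss_parts = [&]() {
    const double beta = lambda(0), sigma = lambda(1);
    rowvec SI = Uhat.row(0) % Uhat.row(1);
    rS = D.row(0) + beta * SI;
    rI = D.row(1) - beta * SI + sigma * Uhat.row(1);
    rR = D.row(2) - sigma * Uhat.row(1);
    LossParts p;
    p.ode_S = w_ode(0) * arma::mean(arma::square(rS));
    p.ode_I = w_ode(1) * arma::mean(arma::square(rI));
    p.ode_R = w_ode(2) * arma::mean(arma::square(rR));
    mat E = Uhat - U;
    p.data = 0.0;
    p.ic = 0.0;
    for (int c = 0; c < 3; ++c) {
      p.data += w_data(c) / n * arma::accu(arma::square(E.row(c)));
      p.ic += w_ic(c) * E(c, 0) * E(c, 0);
    }
    p.total = p.ode_S + p.ode_I + p.ode_R + p.ic + p.data;
    return p;
  };

  const int max_records = iterations / std::max(trace_every, 1) + 2;
  mat trace(max_records, 9);
  int n_rec = 0;
  auto record = [&](int it, const LossParts& p) {
    trace(n_rec, 0) = it;
    trace(n_rec, 1) = lambda(0);
    trace(n_rec, 2) = lambda(1);
    trace(n_rec, 3) = p.ode_S;
    trace(n_rec, 4) = p.ode_I;
    trace(n_rec, 5) = p.ode_R;
    trace(n_rec, 6) = p.ic;
    trace(n_rec, 7) = p.data;
    trace(n_rec, 8) = p.total;
    ++n_rec;
  };

  bool diverged = false;
  int adam_t = 0;
  for (int it = 0; it < iterations; ++it) {
    forward();
    LossParts p = loss_parts();
    if (!std::isfinite(p.total)) {
      diverged = true;
      break;
    }
    if (it % trace_every == 0) record(it, p);

    const double beta = lambda(0), sigma = lambda(1);
    rowvec Sh = Uhat.row(0), Ih = Uhat.row(1);

    // dL/d(residual_c), already carrying the mean and squaring factors
    rowvec BS = (2.0 * w_ode(0) / n) * rS;
    rowvec BI = (2.0 * w_ode(1) / n) * rI;
    rowvec BR = (2.0 * w_ode(2) / n) * rR;

    // dL/d(uhat): data + ic terms, then the residual dependence on uhat
    mat Gu = Uhat - U;
    for (int c = 0; c < 3; ++c) Gu.row(c) *= 2.0 * w_data(c) / n;
    for (int c = 0; c < 3; ++c) Gu(c, 0) += 2.0 * w_ic(c) * (Uhat(c, 0) - U(c, 0));
    Gu.row(0) += beta * Ih % (BS - BI);
    Gu.row(1) += beta * Sh % (BS - BI) + sigma * (BI - BR);
    // dL/d(duhat/dt)
    mat Gd(3, n);
    Gd.row(0) = BS;
    Gd.row(1) = BI;
    Gd.row(2) = BR;

    double gbeta = arma::accu((BS - BI) % (Sh % Ih));
    double gsigma = arma::accu((BI - BR) % Ih);

    // reverse pass through both the value path (delta) and tangent path (ct)
    mat delta = Gu, ct = Gd;
    for (int l = L - 1; l >= 0; --l) {
      gW[l] = delta * A[l].t() + ct * V[l].t();
      gb[l] = arma::sum(delta, 1);
      if (l > 0) {
        delta = (W[l].t() * delta) % mask[l - 1];
        ct = (W[l].t() * ct) % mask[l - 1];
      }
    }

    // Adam step
    ++adam_t;
    const double corr1 = 1.0 - std::pow(b1, adam_t);
    const double corr2 = 1.0 - std::pow(b2, adam_t);
    for (int l = 0; l < L; ++l) {
      mW[l] = b1 * mW[l] + (1.0 - b1) * gW[l];
      vW[l] = b2 * vW[l] + (1.0 - b2) * arma::square(gW[l]);
      W[l] -= lr * (mW[l] / corr1) / (arma::sqrt(vW[l] / corr2) + eps);
      mb[l] = b1 * mb[l] + (1.0 - b1) * gb[l];
      vb[l] = b2 * vb[l] + (1.0 - b2) * arma::square(gb[l]);
      b[l] -= lr * (mb[l] / corr1) / (arma::sqrt(vb[l] / corr2) + eps);
    }
    if (!freeze_lambda) {
      vec gl = {gbeta, gsigma};
      ml = b1 * ml + (1.0 - b1) * gl;
      vl = b2 * vl + (1.0 - b2) * arma::square(gl);
      lambda -= lr * (ml / corr1) / (arma::sqrt(vl / corr2) + eps);
    }
  }

  if (!diverged) {
    forward();
    LossParts p = loss_parts();
    if (std::isfinite(p.total)) {
      record(iterations, p);
    } else {
      diverged = true;
    }
  }

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = b[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout,
      Rcpp::Named("lambda") = lambda,
      Rcpp::Named("trace") = (n_rec > 0 ? trace.rows(0, n_rec - 1) : mat(0, 9)),
      Rcpp::Named("diverged") = diverged);
}
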