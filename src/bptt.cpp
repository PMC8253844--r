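// Forward simulation and exact backpropagation-through-time gradients for
// the coupled motor-neuron / muscle network.
//
// Discrete-time update (synchronous; all time-(t+1) quantities computed from
// time-t values):
//   x_i(t+1) = a_i x_i(t) + b_i * drive_i(t)
// with a = 1/(1 + Fs*tau), b = Fs*tau/(1 + Fs*tau) = 1 - a, and
//   driveN = Wnn yN + Wmn yM + Gnn xN - rowsum(Gnn).xN
//            + Gmn xM - rowsum(Gmn).xN + Win L + bn
//   driveM = Wnm yN + Gmn' xN - colsum(Gmn).xM + Gmm xM - rowsum(Gmm).xM + bm
// where y = 1/(1+exp(-x)).  Gap matrices are symmetric; masked-off weights
// must already be zeroed by the caller.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }
static inline vec sigm_der(const vec& x) {
  vec s = sigm(x);
  return s % (1.0 - s);
}

// [[Rcpp::export]]
List nmw_forward(const arma::mat& Wnn, const arma::mat& Wmn,
                 const arma::mat& Win, const arma::vec& bn,
                 const arma::mat& Wnm, const arma::vec& bm,
                 const arma::mat& Gnn, const arma::mat& Gmn,
                 const arma::mat& Gmm, const arma::vec& tau_n,
                 const arma::vec& tau_m, double Fs, const arma::mat& L,
                 const arma::vec& x0n, const arma::vec& x0m,
                 bool linear_activation = false) {
  const uword J = Wnn.n_rows, U = Wnm.n_rows, T = L.n_rows;
  vec alphaN = 1.0 / (1.0 + Fs * tau_n), betaN = 1.0 - alphaN;
  vec alphaM = 1.0 / (1.0 + Fs * tau_m), betaM = 1.0 - alphaM;
  vec rgnn = sum(Gnn, 1), rgmn_n = sum(Gmn, 1);
  vec rgmn_m = sum(Gmn, 0).t(), rgmm = sum(Gmm, 1);

  mat Xn(T + 1, J), Xm(T + 1, U), DriveN(T, J), DriveM(T, U);
  Xn.row(0) = x0n.t();
  Xm.row(0) = x0m.t();
  vec xN = x0n, xM = x0m;
  for (uword t = 0; t < T; ++t) {
    vec yN = linear_activation ? xN : sigm(xN);
    vec yM = linear_activation ? xM : sigm(xM);
    vec dN = Wnn * yN + Wmn * yM + Gnn * xN - (rgnn + rgmn_n) % xN +
             Gmn * xM + Win * L.row(t).t() + bn;
    vec dM = Wnm * yN + Gmn.t() * xN + Gmm * xM - (rgmn_m + rgmm) % xM + bm;
    xN = alphaN % xN + betaN % dN;
    xM = alphaM % xM + betaM % dM;
    DriveN.row(t) = dN.t();
    DriveM.row(t) = dM.t();
    Xn.row(t + 1) = xN.t();
    Xm.row(t + 1) = xM.t();
  }
  mat Yn = Xn.rows(1, T), Ym = Xm.rows(1, T);
  if (!linear_activation) {
    Yn = 1.0 / (1.0 + exp(-Yn));
    Ym = 1.0 / (1.0 + exp(-Ym));
  }
  return List::create(Named("Xn") = Xn, Named("Xm") = Xm,
                      Named("Yn") = Yn, Named("Ym") = Ym,
                      Named("DriveN") = DriveN, Named("DriveM") = DriveM);
}

// Evaluation function E = (1/T)(1/U) sum_t sum_u 0.5 (yM - d)^2 and its
// exact gradients with respect to every parameter, through the full
// unrolled recursion.  Gap gradients are returned tied: entry (i,j) of gGnn
// is the derivative with respect to the single parameter shared by the
// (i,j) and (j,i) slots.
// [[Rcpp::export]]
List nmw_bptt(const arma::mat& Wnn, const arma::mat& Wmn,
              const arma::mat& Win, const arma::vec& bn,
              const arma::mat& Wnm, const arma::vec& bm,
              const arma::mat& Gnn, const arma::mat& Gmn,
              const arma::mat& Gmm, const arma::vec& tau_n,
              const arma::vec& tau_m, double Fs, const arma::mat& L,
              const arma::vec& x0n, const arma::vec& x0m,
              const arma::mat& d) {
  const uword J = Wnn.n_rows, U = Wnm.n_rows, T = L.n_rows;
  vec alphaN = 1.0 / (1.0 + Fs * tau_n), betaN = 1.0 - alphaN;
  vec alphaM = 1.0 / (1.0 + Fs * tau_m), betaM = 1.0 - alphaM;
  vec rgnn = sum(Gnn, 1), rgmn_n = sum(Gmn, 1);
  vec rgmn_m = sum(Gmn, 0).t(), rgmm = sum(Gmm, 1);
  vec dfacN = Fs / square(1.0 + Fs * tau_n);
  vec dfacM = Fs / square(1.0 + Fs * tau_m);
  const double c = 1.0 / (double(T) * double(U));

  // ---- forward pass, storing states and drives
  mat Xn(T + 1, J), Xm(T + 1, U), DriveN(T, J), DriveM(T, U);
  Xn.row(0) = x0n.t();
  Xm.row(0) = x0m.t();
  {
    vec xN = x0n, xM = x0m;
    for (uword t = 0; t < T; ++t) {
      vec yN = sigm(xN), yM = sigm(xM);
      vec dN = Wnn * yN + Wmn * yM + Gnn * xN - (rgnn + rgmn_n) % xN +
               Gmn * xM + Win * L.row(t).t() + bn;
      vec dM = Wnm * yN + Gmn.t() * xN + Gmm * xM - (rgmn_m + rgmm) % xM +
               bm;
      xN = alphaN % xN + betaN % dN;
      xM = alphaM % xM + betaM % dM;
      DriveN.row(t) = dN.t();
      DriveM.row(t) = dM.t();
      Xn.row(t + 1) = xN.t();
      Xm.row(t + 1) = xM.t();
    }
  }

  double E = 0.0;
  for (uword t = 1; t <= T; ++t) {
    vec e = sigm(Xm.row(t).t()) - d.row(t - 1).t();
    E += 0.5 * dot(e, e);
  }
  E *= c;

  // ---- backward pass
  mat gWnn(J, J, fill::zeros), gWmn(J, U, fill::zeros),
      gWin(J, Win.n_cols, fill::zeros), gWnm(U, J, fill::zeros);
  vec gbn(J, fill::zeros), gbm(U, fill::zeros);
  mat Mnn(J, J, fill::zeros), Mmn1(J, U, fill::zeros),
      Mmn2(J, U, fill::zeros), Mmm(U, U, fill::zeros);
  vec cN(J, fill::zeros), cM(U, fill::zeros);
  vec gtau_n(J, fill::zeros), gtau_m(U, fill::zeros);

  auto deltaM = [&](uword t) -> vec {  // direct loss term at step t
    vec xm = Xm.row(t).t();
    return c * (sigm(xm) - d.row(t - 1).t()) % sigm_der(xm);
  };

  vec lamN(J, fill::zeros), lamM = deltaM(T);
  for (uword s = T; s-- > 0;) {  // s = T-1 .. 0; lam currently at step s+1
    vec nuN = betaN % lamN, nuM = betaM % lamM;
    vec xN_s = Xn.row(s).t(), xM_s = Xm.row(s).t();
    vec yN_s = sigm(xN_s), yM_s = sigm(xM_s);

    gWnn += nuN * yN_s.t();
    gWmn += nuN * yM_s.t();
    gWin += nuN * L.row(s);
    gbn += nuN;
    gWnm += nuM * yN_s.t();
    gbm += nuM;
    Mnn += nuN * xN_s.t();
    Mmn1 += nuN * xM_s.t();
    Mmn2 += xN_s * nuM.t();
    Mmm += nuM * xM_s.t();
    cN += nuN % xN_s;
    cM += nuM % xM_s;
    gtau_n += lamN % dfacN % (DriveN.row(s).t() - xN_s);
    gtau_m += lamM % dfacM % (DriveM.row(s).t() - xM_s);

    if (s >= 1) {  // propagate adjoints to step s
      vec SnS = sigm_der(xN_s), SmS = sigm_der(xM_s);
      vec newLamN = alphaN % lamN + SnS % (Wnn.t() * nuN) + Gnn.t() * nuN -
                    (rgnn + rgmn_n) % nuN + SnS % (Wnm.t() * nuM) +
                    Gmn * nuM;
      vec newLamM = deltaM(s) + SmS % (Wmn.t() * nuN) + Gmn.t() * nuN +
                    alphaM % lamM + Gmm.t() * nuM - (rgmm + rgmn_m) % nuM;
      lamN = newLamN;
      lamM = newLamM;
    }
  }

  mat GamNN = Mnn;
  GamNN.each_col() -= cN;
  mat gGnn = GamNN + GamNN.t();
  gGnn.diag().zeros();

  mat gGmn = Mmn1;
  gGmn.each_col() -= cN;
  mat part2 = Mmn2;
  part2.each_row() -= cM.t();
  gGmn += part2;

  mat GamMM = Mmm;
  GamMM.each_col() -= cM;
  mat gGmm = GamMM + GamMM.t();
  gGmm.diag().zeros();

  return List::create(
      Named("E") = E, Named("w_nn") = gWnn, Named("w_mn") = gWmn,
      Named("w_in") = gWin, Named("bias_n") = gbn, Named("w_nm") = gWnm,
      Named("bias_m") = gbm, Named("g_nn") = gGnn, Named("g_mn") = gGmn,
      Named("g_mm") = gGmm, Named("tau_n") = gtau_n,
      Named("tau_m") = gtau_m);
}
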