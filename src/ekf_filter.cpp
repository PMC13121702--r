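// Stage-1 AFRICO filter pass: joint EKF over reservoir state, input
// weights, state-feedback weights and a provisional linear readout.
// Mirrors the R reference implementation (ekf_predict / ekf_update)
// step for step; equivalence is asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double spec_radius(const mat& A) {
  cx_vec ev = eig_gen(A);
  return max(abs(ev));
}

// rescale W_fb by bisection so that rho(W + W_in * g * W_fb) <= rho_max
static void project_stability(const mat& W, const mat& W_in, mat& W_fb,
                              double rho_max) {
  if (spec_radius(W + W_in * W_fb) <= rho_max) return;
  double lo = 0.0, hi = 1.0;
  for (int i = 0; i < 40; ++i) {
    double mid = 0.5 * (lo + hi);
    if (spec_radius(W + W_in * (mid * W_fb)) > rho_max) hi = mid; else lo = mid;
  }
  W_fb *= lo;
}

// [[Rcpp::export(name = ".africo_stage1_cpp")]]
Rcpp::List africo_stage1_cpp(const arma::mat& W, const arma::mat& W_in0,
                             const arma::mat& W_fb0, const arma::vec& W_out0,
                             const arma::mat& U, const arma::vec& Z,
                             double alpha, double q_state, double q_weights,
                             double r, int epochs, bool use_tanh,
                             double rho_max_cl, double divergence_limit) {
  const uword N = W.n_rows, m = U.n_cols, T = U.n_rows;
  const uword nwin = N * m, nwfb = m * N;
  const uword dim = N + nwin + nwfb + N;
  const uword i_win = N, i_wfb = N + nwin, i_out = N + nwin + nwfb;

  vec mean(dim, fill::zeros);
  mean.subvec(i_win, i_wfb - 1) = vectorise(W_in0);
  mean.subvec(i_wfb, i_out - 1) = vectorise(W_fb0);
  mean.subvec(i_out, dim - 1) = W_out0;
  mat P(dim, dim, fill::eye);
  P *= alpha;
  vec Qdiag(dim);
  Qdiag.fill(q_weights);
  Qdiag.subvec(0, N - 1).fill(q_state);

  vec innov(T * (uword)epochs), Svar(T * (uword)epochs), pnorm(T * (uword)epochs);
  int resets = 0;
  uword step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    mean.subvec(0, N - 1).zeros();
    for (uword k = 0; k < T; ++k) {
      // ---- predict -----------------------------------------------------
      vec x = mean.subvec(0, N - 1);
      mat Wi(&mean[i_win], N, m, false, true);   // views onto the mean
      mat Wf(&mean[i_wfb], m, N, false, true);
      mat A_cl = W + Wi * Wf;
      vec u = U.row(k).t();
      vec v = Wf * x + u;
      vec s = A_cl * x + Wi * u;
      vec x_new(N), d(N);
      if (use_tanh) { x_new = tanh(s); d = 1.0 - square(x_new); }
      else { x_new = s; d.ones(); }
      if (!x_new.is_finite() || abs(x_new).max() > divergence_limit)
        Rcpp::stop("EKF divergence at epoch %d, step %d", ep + 1, (int)k + 1);

      // M0 = B * P with B = [A_cl | kron(v', I_N) | kron(x', W_in) | 0]
      mat M0 = A_cl * P.rows(0, N - 1);
      for (uword j = 0; j < m; ++j)
        M0 += v(j) * P.rows(i_win + j * N, i_win + (j + 1) * N - 1);
      {
        mat S_fb(m, dim, fill::zeros);
        for (uword j = 0; j < N; ++j)
          S_fb += x(j) * P.rows(i_wfb + j * m, i_wfb + (j + 1) * m - 1);
        M0 += Wi * S_fb;
      }
      // C0 = M0 * B'
      mat C0 = M0.cols(0, N - 1) * A_cl.t();
      for (uword j = 0; j < m; ++j)
        C0 += v(j) * M0.cols(i_win + j * N, i_win + (j + 1) * N - 1);
      {
        mat Sc(N, m, fill::zeros);
        for (uword j = 0; j < N; ++j)
          Sc += x(j) * M0.cols(i_wfb + j * m, i_wfb + (j + 1) * m - 1);
        C0 += Sc * Wi.t();
      }
      mat TL = C0;
      TL.each_col() %= d;
      TL.each_row() %= d.t();
      TL = 0.5 * (TL + TL.t());
      mat TR = M0.cols(N, dim - 1);
      TR.each_col() %= d;

      P.submat(0, 0, N - 1, N - 1) = TL;
      P.submat(0, N, N - 1, dim - 1) = TR;
      P.submat(N, 0, dim - 1, N - 1) = TR.t();
      P.diag() += Qdiag;
      mean.subvec(0, N - 1) = x_new;

      // ---- update ------------------------------------------------------
      x = x_new;
      vec w_out = mean.subvec(i_out, dim - 1);
      double yhat = dot(w_out, x);
      double e = Z(k) - yhat;
      vec Pc = P.cols(0, N - 1) * w_out + P.cols(i_out, dim - 1) * x;
      double S = dot(w_out, Pc.subvec(0, N - 1)) +
                 dot(x, Pc.subvec(i_out, dim - 1)) + r;
      if (S <= 0) Rcpp::stop("non-positive innovation variance");
      vec K = Pc / S;
      mean += K * e;
      // Joseph form
      P -= K * Pc.t();
      vec Ac = P.cols(0, N - 1) * w_out + P.cols(i_out, dim - 1) * x;
      P -= (Ac - r * K) * K.t();
      P = 0.5 * (P + P.t());

      innov(step) = e;
      Svar(step) = S;
      double pn = 0;
      for (uword j = N; j < dim; ++j) pn += mean(j) * mean(j);
      pnorm(step) = std::sqrt(pn);
      ++step;

      if (abs(mean.subvec(0, N - 1)).max() > 1e3) {
        mean.subvec(0, N - 1).zeros();
        mat Wf2(&mean[i_wfb], m, N, false, true);
        mat Wi2(&mean[i_win], N, m, false, true);
        mat Wf_copy = Wf2;
        project_stability(W, Wi2, Wf_copy, rho_max_cl);
        Wf2 = Wf_copy;
        ++resets;
      }
      if (!mean.is_finite() || abs(mean).max() > divergence_limit)
        Rcpp::stop("EKF divergence at epoch %d, step %d", ep + 1, (int)k + 1);
    }
  }
  {
    mat Wi(&mean[i_win], N, m, false, true);
    mat Wf(&mean[i_wfb], m, N, false, true);
    mat Wf_copy = Wf;
    project_stability(W, Wi, Wf_copy, rho_max_cl);
    Wf = Wf_copy;
  }
  return Rcpp::List::create(
    Rcpp::Named("W_in") = mat(&mean[i_win], N, m),
    Rcpp::Named("W_fb") = mat(&mean[i_wfb], m, N),
    Rcpp::Named("W_out") = vec(mean.subvec(i_out, dim - 1)),
    Rcpp::Named("final_state") = vec(mean.subvec(0, N - 1)),
    Rcpp::Named("innovation") = innov,
    Rcpp::Named("S") = Svar,
    Rcpp::Named("param_norm") = pnorm,
    Rcpp::Named("resets") = resets);
}
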