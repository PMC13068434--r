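// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Kuramoto right-hand side: dtheta_i = omega_i + (1/N) sum_j K_ij sin(theta_j - theta_i).
// Expanded via sin(a-b) so the coupling sum is two matrix-vector products.
static inline vec kuramoto_rhs(const vec& theta, const vec& omega,
                               const mat& K, const double invN) {
  const vec s = sin(theta);
  const vec c = cos(theta);
  return omega + (c % (K * s) - s % (K * c)) * invN;
}

//' Integrate the Kuramoto phase equations with classical RK4.
//'
//' @param theta0 initial phases (radians), length N.
//' @param omega intrinsic angular frequencies (rad/s), length N.
//' @param K coupling matrix (N x N), units rad/s.
//' @param dt output time step (s).
//' @param nsteps number of output steps; output has nsteps + 1 rows.
//' @param substeps internal RK4 substeps per output step.
//' @return matrix of unwrapped phases, (nsteps + 1) x N.
//' @noRd
// [[Rcpp::export(name = ".kuramoto_rk4")]]
arma::mat kuramoto_rk4(const arma::vec& theta0, const arma::vec& omega,
                       const arma::mat& K, double dt, int nsteps,
                       int substeps) {
  const int N = theta0.n_elem;
  const double invN = 1.0 / N;
  const double h = dt / substeps;
  mat out(nsteps + 1, N);
  vec th = theta0;
  out.row(0) = th.t();
  for (int i = 1; i <= nsteps; ++i) {
    for (int m = 0; m < substeps; ++m) {
      const vec k1 = kuramoto_rhs(th, omega, K, invN);
      const vec k2 = kuramoto_rhs(th + 0.5 * h * k1, omega, K, invN);
      const vec k3 = kuramoto_rhs(th + 0.5 * h * k2, omega, K, invN);
      const vec k4 = kuramoto_rhs(th + h * k3, omega, K, invN);
      th += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    out.row(i) = th.t();
  }
  return out;
}
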