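#include <Rcpp.h>
using namespace Rcpp;

// Euler--Maruyama integration of the network Kuramoto SDE
//   dtheta_i = [2*pi*f + (K/N) sum_j w_ij sin(theta_j - theta_i)] dt
//              + sqrt(2 D dt) xi_i
// with w_ij the coupling from region j onto region i.  The coupling sum is
// evaluated from a per-step snapshot of sin/cos via the angle-difference
// identity, so the update is a proper simultaneous Euler step.
// Phases are recorded wrapped to (-pi, pi] every `record_every` steps,
// starting after `transient_steps`.
// [[Rcpp::export]]
NumericMatrix kuramoto_core(const NumericMatrix& W, double K, double f,
                            double D, double dt, int n_steps,
                            int transient_steps, int record_every,
                            const NumericVector& theta0) {
  const int N = W.nrow();
  if (W.ncol() != N) stop("weight matrix must be square");
  if (theta0.size() != N) stop("initial phase vector does not match connectome size");
  const int rec_steps = n_steps - transient_steps;
  const int n_rec = rec_steps / record_every;
  NumericMatrix out(N, n_rec);

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> sn(N), cs(N);
  const double omega = 2.0 * M_PI * f;
  const double noise_amp = std::sqrt(2.0 * D * dt);
  const double Kn = K / N;

  RNGScope scope;
  int ri = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) {
      sn[i] = std::sin(th[i]);
      cs[i] = std::cos(th[i]);
    }
    for (int i = 0; i < N; ++i) {
      double acc_s = 0.0, acc_c = 0.0;
      for (int j = 0; j < N; ++j) {
        const double w = W(i, j);
        acc_s += w * sn[j];
        acc_c += w * cs[j];
      }
      // sum_j w_ij sin(theta_j - theta_i)
      const double coupling = Kn * (acc_s * cs[i] - acc_c * sn[i]);
      double dth = (omega + coupling) * dt;
      if (D > 0.0) dth += noise_amp * norm_rand();
      th[i] += dth;
    }
    if (step > transient_steps && (step - transient_steps) % record_every == 0) {
      if (ri < n_rec) {
        for (int i = 0; i < N; ++i) {
          // wrap to (-pi, pi]
          const double two_pi = 2.0 * M_PI;
          double x = th[i] - two_pi * std::floor(th[i] / two_pi);
          if (x > M_PI) x -= two_pi;
          out(i, ri) = x;
        }
        ++ri;
      }
    }
  }
  return out;
}
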