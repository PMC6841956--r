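#include <Rcpp.h>
using namespace Rcpp;

// Population-scale actor-critic learning loop.
//
// Individuals are stored group-major: indices [k*g, (k+1)*g) form group k.
// Per round, each individual draws an investment from Normal(theta, sigma),
// receives the perceived reward B(abar) - K(a, p_i), and applies the critic
// then the actor update from its own TD error. Actions within a round are
// drawn from the pre-round states (synchronous update). Draw order is fixed
// (group, then member, then round) so a given R RNG seed reproduces the
// pure-R round loop exactly for a single group.
//
// Returns final states, each individual's mean TRUE-quality payoff over the
// T rounds (the Darwinian fitness used by selection), and, if record = true,
// the full per-round trajectories.
// [[Rcpp::export]]
List learn_kernel(NumericVector w0, NumericVector theta0,
                  NumericVector p, NumericVector q,
                  int g, int T,
                  double B0, double B1, double B2,
                  double K1, double K11, double K12,
                  double sigma, double alpha_w, double alpha_theta,
                  bool clamp, double a_max, bool record) {
  const int n = w0.size();
  if (n % g != 0) stop("population size must be a multiple of g");
  const int ngroups = n / g;
  const double s2 = sigma * sigma;

  NumericVector w = clone(w0);
  NumericVector theta = clone(theta0);
  NumericVector fitness(n);
  std::vector<double> a(g);

  NumericMatrix rec_a, rec_r, rec_d, rec_w, rec_th;
  if (record) {
    rec_a = NumericMatrix(T, n);
    rec_r = NumericMatrix(T, n);
    rec_d = NumericMatrix(T, n);
    rec_w = NumericMatrix(T, n);
    rec_th = NumericMatrix(T, n);
  }

  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < ngroups; ++k) {
      const int off = k * g;
      // long-double accumulation and explicit association chosen to
      // reproduce the pure-R round loop bit for bit on the same seed
      long double sum = 0.0;
      for (int j = 0; j < g; ++j) {
        double aj = R::rnorm(theta[off + j], sigma);
        if (clamp && aj > a_max) aj = a_max;
        a[j] = aj;
        sum += aj;
      }
      const double abar = (double)sum / g;
      const double bnf = B0 + B1 * abar + (0.5 * B2) * (abar * abar);
      for (int j = 0; j < g; ++j) {
        const int i = off + j;
        const double aj = a[j];
        const double reward = bnf - (K1 * aj + (0.5 * K11) * (aj * aj) +
                                     (K12 * aj) * p[i]);
        const double delta = reward - w[i];
        const double zeta = (aj - theta[i]) / s2;
        fitness[i] += bnf - (K1 * aj + (0.5 * K11) * (aj * aj) +
                             (K12 * aj) * q[i]);
        w[i] += alpha_w * delta;
        theta[i] += alpha_theta * delta * zeta;
        if (record) {
          rec_a(t, i) = aj;
          rec_r(t, i) = reward;
          rec_d(t, i) = delta;
          rec_w(t, i) = w[i];
          rec_th(t, i) = theta[i];
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) fitness[i] /= T;

  List out = List::create(_["w"] = w, _["theta"] = theta,
                          _["fitness"] = fitness);
  if (record) {
    out["actions"] = rec_a;
    out["rewards"] = rec_r;
    out["deltas"] = rec_d;
    out["w_traj"] = rec_w;
    out["theta_traj"] = rec_th;
  }
  return out;
}
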