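// Euler-Maruyama integration of the theta-neuron network model.
//
// Node phase update (dimensionless time, step dt):
//   dtheta_j = [(1 - cos th_j) + (1 + cos th_j) * I_j] dt + (1 + cos th_j) * noise
//   I_j      = i0 + (K/N) * sum_i a_ij * (1 - cos(th_i - th_s))
// where th_s is the stable fixed point of the uncoupled node and `noise`
// already carries the full sigma * sqrt(dt) * eta Euler-Maruyama increment.
//
// The per-sample epileptiform state uses the saddle-crossing rule: a node
// becomes epileptiform when its phase crosses the unstable fixed point th_u
// in the increasing direction, and returns to the normal state when the
// phase next crosses the stable point th_s in the increasing direction
// (i.e. completes the rotation back into the resting basin). Both crossing
// checks are wrap-aware.
//
// Written for throughput: virtual-resection searches evaluate this loop for
// tens of thousands of perturbed networks. The coupling term uses sparse
// in-edge lists; the trigonometric refresh runs in single precision over
// flat arrays so the compiler can vectorize it (phase error ~1e-7 rad per
// step, far below the stochastic forcing and the Euler O(dt) bias).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// hot path: make sure this translation unit is built at full optimization
// even when the site-wide CXXFLAGS end in a lower level
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;
static const double TWO_PI = 6.28318530717958647692;

static inline double wrap_pi(double x) {
  // wrap to (-pi, pi]
  if (x > PI_ || x <= -PI_) {
    x -= TWO_PI * std::nearbyint(x / TWO_PI);
    if (x <= -PI_) x += TWO_PI;
    else if (x > PI_) x -= TWO_PI;
  }
  return x;
}

// branchless float sin/cos over an array of wrapped phases; quadrant
// reduction to |r| <= pi/4 plus short odd/even polynomials
static void sincos_arr(const double* th, float* s, float* c, int n) {
  for (int j = 0; j < n; ++j) {
    float x = (float)th[j];
    float qf = x * 0.636619772f;  // x / (pi/2)
    int q = (int)(qf + (qf >= 0.0f ? 0.5f : -0.5f));
    float r = x - q * 1.57079632679f;
    float r2 = r * r;
    float sr = r * (1.0f + r2 * (-1.0f / 6.0f + r2 * (1.0f / 120.0f - r2 / 5040.0f)));
    float cr = 1.0f + r2 * (-0.5f + r2 * (1.0f / 24.0f +
               r2 * (-1.0f / 720.0f + r2 / 40320.0f)));
    int qa = q & 1;
    float s0 = qa ? cr : sr, c0 = qa ? sr : cr;
    s[j] = (q & 2) ? -s0 : s0;
    c[j] = ((q + 1) & 2) ? -c0 : c0;
  }
}

// Does the increasing move from wrapped phase a by delta > 0 cross target?
static inline bool crosses_up(double a, double delta, double target) {
  double t = target;
  if (t <= a) t += TWO_PI;
  return a + delta >= t;
}

// noise_cols: 1-based columns of `noise` feeding each of the n nodes, so a
// subnetwork run can stream from the full common-random-number noise matrix
// without copying. k_total divides the coupling sum (K/N of the full model)
// even when only a subnetwork is simulated.
// [[Rcpp::export(name = ".theta_sim_core")]]
List theta_sim_core(const NumericMatrix& w, double k, double i0, double dt,
                    int n_steps, double theta_s, double theta_u,
                    const NumericMatrix& noise, const IntegerVector& noise_cols,
                    int n_total, const NumericVector& theta0,
                    bool return_trace) {
  const int n = w.nrow();
  if (w.ncol() != n) stop("adjacency matrix must be square");
  if (noise.nrow() != n_steps) stop("noise must have n_steps rows");
  if (noise_cols.size() != n) stop("noise_cols must have length n");
  for (int j = 0; j < n; ++j)
    if (noise_cols[j] < 1 || noise_cols[j] > noise.ncol())
      stop("noise_cols out of range");
  if (n_total < n) stop("n_total must be >= n");
  if (theta0.size() != n) stop("theta0 must have length n");

  // sparse in-edge lists: inputs to node j are rows i of column j
  std::vector<int> in_start(n + 1, 0);
  std::vector<int> in_idx;
  std::vector<float> in_w;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      double wij = w(i, j);
      if (wij != 0.0) { in_idx.push_back(i); in_w.push_back((float)wij); }
    }
    in_start[j + 1] = (int)in_idx.size();
  }

  std::vector<double> th(n);
  std::vector<float> cth(n), sth(n), sdrive(n);
  std::vector<uint8_t> state(n, 0);
  std::vector<long> count(n, 0);

  float cs, ss;
  {
    double tsw = wrap_pi(theta_s);
    sincos_arr(&tsw, &ss, &cs, 1);
  }
  for (int j = 0; j < n; ++j) th[j] = wrap_pi(theta0[j]);
  sincos_arr(th.data(), sth.data(), cth.data(), n);
  for (int j = 0; j < n; ++j) sdrive[j] = 1.0f - (cth[j] * cs + sth[j] * ss);

  NumericMatrix trace;
  if (return_trace) trace = NumericMatrix(n_steps, n);

  const double kn = (n_total > 0) ? k / n_total : 0.0;
  const double* noisep = (n_steps > 0 && noise.ncol() > 0) ? &noise(0, 0) : NULL;
  std::vector<const double*> ncol(n);
  for (int j = 0; j < n; ++j)
    ncol[j] = noisep + (size_t)(noise_cols[j] - 1) * n_steps;

  for (int t = 0; t < n_steps; ++t) {
    for (int j = 0; j < n; ++j) {
      float coup = 0.0f;
      for (int e = in_start[j]; e < in_start[j + 1]; ++e)
        coup += in_w[e] * sdrive[in_idx[e]];
      double cj = (double)cth[j];
      double omc = 1.0 - cj, opc = 1.0 + cj;
      double delta = (omc + opc * (i0 + kn * coup)) * dt + opc * ncol[j][t];
      if (delta > 0.0) {
        if (state[j] == 1 && crosses_up(th[j], delta, theta_s)) state[j] = 0;
        if (state[j] == 0 && crosses_up(th[j], delta, theta_u)) state[j] = 1;
      }
      count[j] += state[j];
      th[j] = wrap_pi(th[j] + delta);
      if (return_trace) trace(t, j) = th[j];
    }
    sincos_arr(th.data(), sth.data(), cth.data(), n);
    for (int j = 0; j < n; ++j) sdrive[j] = 1.0f - (cth[j] * cs + sth[j] * ss);
    if ((t & 1023) == 0) {
      for (int j = 0; j < n; ++j)
        if (!std::isfinite(th[j]))
          stop("phase blow-up (non-finite) near step %d, node %d", t + 1, j + 1);
    }
  }

  NumericVector frac(n), final_theta(n);
  for (int j = 0; j < n; ++j) {
    if (!std::isfinite(th[j]))
      stop("phase blow-up (non-finite) at final step, node %d", j + 1);
    frac[j] = n_steps > 0 ? (double)count[j] / n_steps : 0.0;
    final_theta[j] = th[j];
  }
  List out = List::create(_["seizure_fraction"] = frac,
                          _["final_theta"] = final_theta);
  if (return_trace) out["trace"] = trace;
  return out;
}
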