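#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler-Maruyama integration of a 2-D Gaussian-well potential
//   U(x) = -sum_w depth_w * exp(-0.5 * sum_a (x_a - c_wa)^2 / sigma_wa^2)
//          + confinement * |x|^2
// noise is a (n_steps-1) x 2 matrix of standard normal draws; the first
// output row is the initial position, so the trajectory has n_steps rows.
// [[Rcpp::export]]
NumericMatrix langevin_cpp(NumericMatrix centers, NumericVector depths,
                           NumericMatrix widths, double confinement,
                           double kT, NumericVector x0, int n_steps,
                           double dt, double diffusion, NumericMatrix noise) {
  const int W = centers.nrow();
  NumericMatrix out(n_steps, 2);
  double x = x0[0], y = x0[1];
  const double pref = diffusion / kT * dt;
  const double amp = std::sqrt(2.0 * diffusion * dt);
  out(0, 0) = x;
  out(0, 1) = y;
  for (int t = 1; t < n_steps; ++t) {
    double gx = 2.0 * confinement * x;
    double gy = 2.0 * confinement * y;
    for (int w = 0; w < W; ++w) {
      const double dx = x - centers(w, 0);
      const double dy = y - centers(w, 1);
      const double sx2 = widths(w, 0) * widths(w, 0);
      const double sy2 = widths(w, 1) * widths(w, 1);
      const double e = depths[w] * std::exp(-0.5 * (dx * dx / sx2 + dy * dy / sy2));
      gx += e * dx / sx2;
      gy += e * dy / sy2;
    }
    if (!R_finite(gx) || !R_finite(gy))
      stop("non-finite force at step %d", t);
    x += -pref * gx + amp * noise(t - 1, 0);
    y += -pref * gy + amp * noise(t - 1, 1);
    out(t, 0) = x;
    out(t, 1) = y;
  }
  return out;
}

// Sample a discrete Markov chain from row-wise cumulative probabilities.
// u holds length(out)-1 uniform draws; out[0] is the initial state (0-based).
// [[Rcpp::export]]
IntegerVector markov_sample_cpp(NumericMatrix cumP, int init, NumericVector u) {
  const int n = u.size() + 1;
  const int K = cumP.ncol();
  IntegerVector out(n);
  int s = init;
  out[0] = s;
  for (int t = 1; t < n; ++t) {
    const double uu = u[t - 1];
    int j = 0;
    while (j < K - 1 && uu > cumP(s, j)) ++j;
    s = j;
    out[t] = s;
  }
  return out;
}

// Nearest-centre assignment (squared Euclidean), 0-based indices.
// [[Rcpp::export]]
List assign_nearest_cpp(NumericMatrix X, NumericMatrix C) {
  const int n = X.nrow(), k = C.nrow(), d = X.ncol();
  IntegerVector a(n);
  NumericVector dist2(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        const double dd = X(i, m) - C(j, m);
        s += dd * dd;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    a[i] = bj;
    dist2[i] = best;
  }
  return List::create(_["cluster"] = a, _["dist2"] = dist2);
}

// Reversible maximum-likelihood transition matrix from a count matrix via the
// standard self-consistent iteration on the symmetrized sufficient statistics
// x_ij, converged when max |T_new - T_old| < tol.
// [[Rcpp::export]]
List reversible_mle_cpp(NumericMatrix C, double tol, int maxiter) {
  const int K = C.nrow();
  NumericMatrix x(K, K), xnew(K, K), T(K, K), Told(K, K);
  NumericVector ci(K), xi(K);
  for (int i = 0; i < K; ++i) {
    double s = 0.0;
    for (int j = 0; j < K; ++j) {
      x(i, j) = C(i, j) + C(j, i);
      s += C(i, j);
    }
    ci[i] = s;
  }
  double delta = R_PosInf;
  int iter = 0;
  while (delta > tol && iter < maxiter) {
    ++iter;
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += x(i, j);
      xi[i] = s;
    }
    for (int i = 0; i < K; ++i) {
      for (int j = i; j < K; ++j) {
        const double num = C(i, j) + C(j, i);
        double val = 0.0;
        if (num > 0.0)
          val = num / (ci[i] / xi[i] + ci[j] / xi[j]);
        xnew(i, j) = val;
        xnew(j, i) = val;
      }
    }
    delta = 0.0;
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += xnew(i, j);
      for (int j = 0; j < K; ++j) {
        T(i, j) = s > 0 ? xnew(i, j) / s : 0.0;
        const double dd = std::fabs(T(i, j) - Told(i, j));
        if (dd > delta) delta = dd;
        Told(i, j) = T(i, j);
      }
    }
    std::swap(x, xnew);
  }
  double tot = 0.0;
  for (int i = 0; i < K; ++i) {
    double s = 0.0;
    for (int j = 0; j < K; ++j) s += x(i, j);
    xi[i] = s;
    tot += s;
  }
  NumericVector pi(K);
  for (int i = 0; i < K; ++i) pi[i] = xi[i] / tot;
  return List::create(_["T"] = T, _["pi"] = pi, _["iterations"] = iter,
                      _["converged"] = (delta <= tol));
}
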