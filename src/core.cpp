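// Fixed-step integrators and the step-input response protocol for
// sigmoidal gene-expression dynamics on signed ternary networks:
//   dx_i/dt = sigmoid(beta * (z_i - theta)) - x_i + delta
//   z_i     = (sum_j J_ij x_j) / s_i + I * [i == input]
// The genetic algorithm evaluates thousands of networks per generation,
// so the inner loops live here rather than in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sig(double z, double beta, double theta) {
  double a = beta * (z - theta);
  if (a > 40.0) return 1.0;     // saturate; exp() would overflow/waste time
  if (a < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-a));
}

// dx/dt at state x; Js is the row-scaled interaction matrix J_ij / s_i
static inline void field(const arma::mat& Js, const arma::vec& x,
                         int input, double I, double beta, double theta,
                         double delta, arma::vec& dx) {
  arma::vec z = Js * x;
  z(input) += I;
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    dx(i) = sig(z(i), beta, theta) - x(i) + delta;
}

// one classical RK4 step (in place)
static inline void rk4_step(const arma::mat& Js, arma::vec& x, int input,
                            double I, double beta, double theta, double delta,
                            double dt, arma::vec& k1, arma::vec& k2,
                            arma::vec& k3, arma::vec& k4, arma::vec& tmp) {
  tmp = x + 0.5 * dt * k1;  // k1 must already hold f(x)
  field(Js, tmp, input, I, beta, theta, delta, k2);
  tmp = x + 0.5 * dt * k2;
  field(Js, tmp, input, I, beta, theta, delta, k3);
  tmp = x + dt * k3;
  field(Js, tmp, input, I, beta, theta, delta, k4);
  x += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

struct RelaxOut {
  arma::vec state;      // converged state, or window average
  bool converged;
  bool oscillatory;
  double time;          // time when criterion met, or t_max
};

// Integrate under constant I until max|dx/dt| <= ss_tol or t reaches t_max.
// If not converged, the mean over the final avg_window is returned and the
// run is flagged oscillatory when the two trailing window means agree to
// osc_tol (stationary but not a fixed point).
static RelaxOut relax_core(const arma::mat& Js, arma::vec x, int input,
                           double I, double beta, double theta, double delta,
                           double dt, double t_max, double ss_tol,
                           double avg_window, double osc_tol) {
  const arma::uword n = x.n_elem;
  const long n_steps = (long)std::ceil(t_max / dt);
  const long w = std::max(1L, (long)std::round(avg_window / dt));
  arma::vec k1(n), k2(n), k3(n), k4(n), tmp(n);
  arma::vec sumA(n, arma::fill::zeros), sumB(n, arma::fill::zeros);
  RelaxOut out;
  for (long step = 0; step < n_steps; ++step) {
    field(Js, x, input, I, beta, theta, delta, k1);
    if (arma::abs(k1).max() <= ss_tol) {
      out.state = x; out.converged = true; out.oscillatory = false;
      out.time = step * dt;
      return out;
    }
    rk4_step(Js, x, input, I, beta, theta, delta, dt, k1, k2, k3, k4, tmp);
    long from_end = n_steps - 1 - step;           // 0 for the last step
    if (from_end < w) sumB += x;
    else if (from_end < 2 * w) sumA += x;
  }
  field(Js, x, input, I, beta, theta, delta, k1);
  if (arma::abs(k1).max() <= ss_tol) {
    out.state = x; out.converged = true; out.oscillatory = false;
    out.time = n_steps * dt;
    return out;
  }
  arma::vec meanA = sumA / (double)w, meanB = sumB / (double)w;
  out.oscillatory = arma::abs(meanA - meanB).max() <= osc_tol;
  out.converged = false;
  out.state = meanB;
  out.time = n_steps * dt;
  return out;
}

// [[Rcpp::export]]
List cpp_relax(const arma::mat& Js, const arma::vec& x0, int input, double I,
               double beta, double theta, double delta, double dt,
               double t_max, double ss_tol, double avg_window,
               double osc_tol) {
  RelaxOut r = relax_core(Js, x0, input, I, beta, theta, delta, dt, t_max,
                          ss_tol, avg_window, osc_tol);
  return List::create(_["state"] = r.state, _["converged"] = r.converged,
                      _["oscillatory"] = r.oscillatory,
                      _["relaxation_time"] = r.time);
}

// [[Rcpp::export]]
arma::mat cpp_integrate(const arma::mat& Js, const arma::vec& x0, int input,
                        double I, double beta, double theta, double delta,
                        double dt, long n_steps, long stride) {
  const arma::uword n = x0.n_elem;
  arma::vec x = x0, k1(n), k2(n), k3(n), k4(n), tmp(n);
  long n_rec = n_steps / stride;
  arma::mat traj(n_rec + 1, n);
  traj.row(0) = x.t();
  long rec = 1;
  for (long step = 1; step <= n_steps; ++step) {
    field(Js, x, input, I, beta, theta, delta, k1);
    rk4_step(Js, x, input, I, beta, theta, delta, dt, k1, k2, k3, k4, tmp);
    if (!x.is_finite())
      stop("non-finite expression state at t = %f", step * dt);
    if (step % stride == 0) traj.row(rec++) = x.t();
  }
  return traj.head_rows(rec);
}

struct RespOut {
  arma::vec baseline, dmax, dstat, dir, final_state;
  bool base_converged, post_converged, post_oscillatory;
  double base_time, post_time;
};

// The canonical evaluation protocol: relax from x0 under I0 to a baseline,
// switch to I1, track per-gene max |x - baseline| (and its sign), and take
// the steady-state deviation from the converged state or, failing
// convergence, from the trailing window average.
static RespOut response_core(const arma::mat& Js, const arma::vec& x0,
                             int input, double I0, double I1, double beta,
                             double theta, double delta, double dt,
                             double t_max, double ss_tol, double avg_window,
                             double osc_tol) {
  const arma::uword n = x0.n_elem;
  RespOut out;
  RelaxOut base = relax_core(Js, x0, input, I0, beta, theta, delta, dt, t_max,
                             ss_tol, avg_window, osc_tol);
  out.baseline = base.state;
  out.base_converged = base.converged;
  out.base_time = base.time;

  arma::vec x = base.state;
  arma::vec k1(n), k2(n), k3(n), k4(n), tmp(n);
  arma::vec dmax(n, arma::fill::zeros), dir(n, arma::fill::ones);
  arma::vec sumA(n, arma::fill::zeros), sumB(n, arma::fill::zeros);
  const long n_steps = (long)std::ceil(t_max / dt);
  const long w = std::max(1L, (long)std::round(avg_window / dt));
  bool converged = false;
  long step = 0;
  for (; step < n_steps; ++step) {
    field(Js, x, input, I1, beta, theta, delta, k1);
    if (arma::abs(k1).max() <= ss_tol) { converged = true; break; }
    rk4_step(Js, x, input, I1, beta, theta, delta, dt, k1, k2, k3, k4, tmp);
    for (arma::uword i = 0; i < n; ++i) {
      double d = x(i) - base.state(i), ad = std::fabs(d);
      if (ad > dmax(i)) { dmax(i) = ad; dir(i) = (d >= 0) ? 1.0 : -1.0; }
    }
    long from_end = n_steps - 1 - step;
    if (from_end < w) sumB += x;
    else if (from_end < 2 * w) sumA += x;
  }
  out.post_converged = converged;
  out.post_time = step * dt;
  out.final_state = x;
  if (converged) {
    out.dstat = arma::abs(x - base.state);
    out.post_oscillatory = false;
  } else {
    arma::vec meanB = sumB / (double)w;
    out.dstat = arma::abs(meanB - base.state);
    out.post_oscillatory =
        arma::abs(sumA / (double)w - meanB).max() <= osc_tol;
    out.final_state = meanB;
  }
  out.dmax = dmax;
  out.dir = dir;
  return out;
}

// [[Rcpp::export]]
List cpp_response(const arma::mat& Js, const arma::vec& x0, int input,
                  double I0, double I1, double beta, double theta,
                  double delta, double dt, double t_max, double ss_tol,
                  double avg_window, double osc_tol) {
  RespOut r = response_core(Js, x0, input, I0, I1, beta, theta, delta, dt,
                            t_max, ss_tol, avg_window, osc_tol);
  return List::create(
      _["baseline"] = r.baseline, _["base_converged"] = r.base_converged,
      _["base_time"] = r.base_time, _["dmax"] = r.dmax, _["dstat"] = r.dstat,
      _["direction"] = r.dir, _["final_state"] = r.final_state,
      _["post_converged"] = r.post_converged,
      _["post_oscillatory"] = r.post_oscillatory, _["post_time"] = r.post_time);
}

// Fitness (target adaptiveness) and average adaptiveness over non-terminal
// genes for a whole population; scale_by_indegree selects the s_i normalizer.
// [[Rcpp::export]]
List cpp_evaluate_population(List Jlist, int input, int target, double I0,
                             double I1, double beta, double theta,
                             double delta, double dt, double t_max,
                             double ss_tol, double avg_window, double osc_tol,
                             bool scale_by_indegree, bool start_on) {
  int M = Jlist.size();
  NumericVector fitness(M), abar(M);
  for (int m = 0; m < M; ++m) {
    IntegerMatrix Ji = Jlist[m];
    const arma::uword n = Ji.nrow();
    arma::mat Js(n, n);
    if (scale_by_indegree) {
      for (arma::uword i = 0; i < n; ++i) {
        double indeg = 0;
        for (arma::uword j = 0; j < n; ++j) indeg += (Ji(i, j) != 0);
        double s = std::sqrt(std::max(1.0, indeg));
        for (arma::uword j = 0; j < n; ++j) Js(i, j) = Ji(i, j) / s;
      }
    } else {
      double s = std::sqrt((double)n);
      for (arma::uword i = 0; i < n; ++i)
        for (arma::uword j = 0; j < n; ++j) Js(i, j) = Ji(i, j) / s;
    }
    arma::vec x0(n);
    x0.fill(start_on ? 1.0 : 0.0);
    RespOut r = response_core(Js, x0, input, I0, I1, beta, theta, delta, dt,
                              t_max, ss_tol, avg_window, osc_tol);
    arma::vec f = r.dmax - r.dstat;
    fitness[m] = f(target);
    double acc = 0.0;
    int cnt = 0;
    for (arma::uword i = 0; i < n; ++i)
      if ((int)i != input && (int)i != target) { acc += f(i); ++cnt; }
    abar[m] = cnt > 0 ? acc / cnt : NA_REAL;
    if (!std::isfinite(fitness[m]))
      stop("non-finite fitness for population member %d", m + 1);
  }
  return List::create(_["fitness"] = fitness, _["abar"] = abar);
}

// Euler-Maruyama trajectory with additive Gaussian white noise of amplitude
// sigma per gene; states clipped to [0, 1 + delta] after each step. Draws
// come from R's RNG so runs are reproducible under set.seed(). sigma = 0
// reduces to deterministic Euler at the same dt.
// [[Rcpp::export]]
arma::mat cpp_noisy_integrate(const arma::mat& Js, const arma::vec& x0,
                              int input, double I, double beta, double theta,
                              double delta, double dt, long n_steps,
                              double sigma, long stride) {
  const arma::uword n = x0.n_elem;
  arma::vec x = x0, dx(n);
  const double sq = sigma * std::sqrt(dt);
  long n_rec = n_steps / stride;
  arma::mat traj(n_rec + 1, n);
  traj.row(0) = x.t();
  long rec = 1;
  for (long step = 1; step <= n_steps; ++step) {
    field(Js, x, input, I, beta, theta, delta, dx);
    if (sigma > 0.0) {
      for (arma::uword i = 0; i < n; ++i)
        x(i) += dt * dx(i) + sq * R::norm_rand();
    } else {
      x += dt * dx;
    }
    for (arma::uword i = 0; i < n; ++i) {
      if (x(i) < 0.0) x(i) = 0.0;
      if (x(i) > 1.0 + delta) x(i) = 1.0 + delta;
    }
    if (step % stride == 0) traj.row(rec++) = x.t();
  }
  return traj.head_rows(rec);
}

// Step-response metrics under expression noise. Both phases are integrated
// with Euler-Maruyama for fixed durations; the baseline and the final level
// are time averages over the trailing avg_window of each phase.
// [[Rcpp::export]]
List cpp_noisy_response(const arma::mat& Js, const arma::vec& x0, int input,
                        double I0, double I1, double beta, double theta,
                        double delta, double dt, double t_pre, double t_post,
                        double avg_window, double sigma) {
  const arma::uword n = x0.n_elem;
  arma::vec x = x0, dx(n);
  const double sq = sigma * std::sqrt(dt);
  const long n_pre = (long)std::ceil(t_pre / dt);
  const long n_post = (long)std::ceil(t_post / dt);
  const long w_pre = std::max(1L, std::min(n_pre, (long)std::round(avg_window / dt)));
  const long w_post = std::max(1L, std::min(n_post, (long)std::round(avg_window / dt)));
  arma::vec acc(n, arma::fill::zeros);
  for (long step = 0; step < n_pre; ++step) {
    field(Js, x, input, I0, beta, theta, delta, dx);
    if (sigma > 0.0)
      for (arma::uword i = 0; i < n; ++i)
        x(i) += dt * dx(i) + sq * R::norm_rand();
    else
      x += dt * dx;
    for (arma::uword i = 0; i < n; ++i) {
      if (x(i) < 0.0) x(i) = 0.0;
      if (x(i) > 1.0 + delta) x(i) = 1.0 + delta;
    }
    if (n_pre - 1 - step < w_pre) acc += x;
  }
  arma::vec baseline = acc / (double)w_pre;
  arma::vec dmax(n, arma::fill::zeros), dir(n, arma::fill::ones);
  acc.zeros();
  for (long step = 0; step < n_post; ++step) {
    field(Js, x, input, I1, beta, theta, delta, dx);
    if (sigma > 0.0)
      for (arma::uword i = 0; i < n; ++i)
        x(i) += dt * dx(i) + sq * R::norm_rand();
    else
      x += dt * dx;
    for (arma::uword i = 0; i < n; ++i) {
      if (x(i) < 0.0) x(i) = 0.0;
      if (x(i) > 1.0 + delta) x(i) = 1.0 + delta;
      double d = x(i) - baseline(i), ad = std::fabs(d);
      if (ad > dmax(i)) { dmax(i) = ad; dir(i) = (d >= 0) ? 1.0 : -1.0; }
    }
    if (n_post - 1 - step < w_post) acc += x;
  }
  arma::vec dstat = arma::abs(acc / (double)w_post - baseline);
  return List::create(_["baseline"] = baseline, _["dmax"] = dmax,
                      _["dstat"] = dstat, _["direction"] = dir);
}
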