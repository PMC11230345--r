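// Hybrid Euler-Maruyama / Markov-switching integrator for the bead model.
// Positions follow dx = v(x; s) dt + sqrt(2 eps) dB with v the sum of
// confinement, excluded-volume and crosslink-spring forces; the binding
// state s is advanced per step by Bernoulli thinning with rates frozen at
// the updated positions.  Uses R's RNG throughout so set.seed() gives
// bit-identical replays.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Pars {
  int n, dim;
  double eta, a_ev, c_ev, kappa, c_break;
  double amp, steep, mid;
  double eps;
};

static Pars read_pars(const List& par, int n, int dim) {
  Pars P;
  P.n = n; P.dim = dim;
  P.eta = as<double>(par["eta"]);
  P.a_ev = as<double>(par["a_ev"]);
  P.c_ev = as<double>(par["c_ev"]);
  P.kappa = as<double>(par["kappa"]);
  P.c_break = as<double>(par["c_break"]);
  P.amp = as<double>(par["affinity_amplitude"]);
  P.steep = as<double>(par["affinity_steepness"]);
  P.mid = as<double>(par["affinity_midpoint"]);
  P.eps = as<double>(par["epsilon"]);
  return P;
}

static inline double affinity_rate(const Pars& P, double r) {
  return P.amp / (1.0 + std::exp(P.steep * (r - P.mid)));
}

// one hybrid step on flattened bead-major coordinates x (length n*dim) and
// 0-based partner array (-1 = unbound); returns false on non-finite x
static bool hybrid_step(std::vector<double>& x, std::vector<int>& part,
                        const Pars& P, double dt, double rate_mult,
                        double p_break, double r_cut2,
                        std::vector<double>& f,
                        std::vector<int>& prop_i, std::vector<int>& prop_j,
                        bool freeze_positions) {
  const int n = P.n, dim = P.dim;
  if (!freeze_positions) {
    // confinement
    for (int k = 0; k < n * dim; ++k) f[k] = -P.eta * x[k];
    // pairwise excluded volume
    if (P.a_ev > 0.0) {
      for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double r2 = 0.0, dxk[3];
          for (int k = 0; k < dim; ++k) {
            dxk[k] = x[i * dim + k] - x[j * dim + k];
            r2 += dxk[k] * dxk[k];
          }
          double g = P.a_ev * std::exp(-r2 / P.c_ev);
          for (int k = 0; k < dim; ++k) {
            f[i * dim + k] += g * dxk[k];
            f[j * dim + k] -= g * dxk[k];
          }
        }
      }
    }
    // crosslink springs
    for (int i = 0; i < n; ++i) {
      int j = part[i];
      if (j >= 0) {
        for (int k = 0; k < dim; ++k)
          f[i * dim + k] += P.kappa * (x[j * dim + k] - x[i * dim + k]);
      }
    }
    double sig = std::sqrt(2.0 * P.eps * dt);
    for (int k = 0; k < n * dim; ++k) {
      x[k] += f[k] * dt + sig * norm_rand();
      if (!std::isfinite(x[k])) return false;
    }
  }
  // eligibility to bind is taken from the pre-break state: a bead freed
  // by a break within this step cannot rebind until the next step
  static std::vector<char> was_bound;
  was_bound.assign(n, 0);
  for (int i = 0; i < n; ++i) if (part[i] >= 0) was_bound[i] = 1;
  // bond breaking
  for (int i = 0; i < n; ++i) {
    int j = part[i];
    if (j > i) {
      if (unif_rand() < p_break) { part[i] = -1; part[j] = -1; }
    }
  }
  // binding proposals among free pairs (distance-cut to skip hopeless pairs)
  prop_i.clear(); prop_j.clear();
  for (int i = 0; i < n - 1; ++i) {
    if (was_bound[i] || part[i] >= 0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (was_bound[j] || part[j] >= 0) continue;
      double r2 = 0.0;
      for (int k = 0; k < dim; ++k) {
        double d = x[i * dim + k] - x[j * dim + k];
        r2 += d * d;
      }
      if (r2 > r_cut2) continue;
      double p_bind = 1.0 - std::exp(-rate_mult * affinity_rate(P, std::sqrt(r2)) * dt);
      if (unif_rand() < p_bind) { prop_i.push_back(i); prop_j.push_back(j); }
    }
  }
  // apply proposals in uniformly random order, dropping conflicts
  int m = (int)prop_i.size();
  for (int k = m - 1; k > 0; --k) {
    int l = (int)std::floor(unif_rand() * (k + 1));
    if (l > k) l = k;
    std::swap(prop_i[k], prop_i[l]);
    std::swap(prop_j[k], prop_j[l]);
  }
  for (int k = 0; k < m; ++k) {
    int i = prop_i[k], j = prop_j[k];
    if (part[i] < 0 && part[j] < 0) { part[i] = j; part[j] = i; }
  }
  return true;
}

static double bind_cut2(const Pars& P, double rate_mult, double dt) {
  // distance beyond which the per-step binding probability is < ~1e-14
  double z = std::max(P.amp * rate_mult * dt * 1e14, 10.0);
  double r = P.mid + std::log(z) / P.steep;
  return r * r;
}

// [[Rcpp::export]]
List sim_switching_cpp(NumericMatrix pos0, IntegerVector partner0, List par,
                       double dt, int n_steps, int record_every,
                       double rate_mult, bool freeze_positions) {
  const int n = pos0.nrow(), dim = pos0.ncol();
  Pars P = read_pars(par, n, dim);
  std::vector<double> x(n * dim);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < dim; ++k) x[i * dim + k] = pos0(i, k);
  std::vector<int> part(n);
  for (int i = 0; i < n; ++i) part[i] = partner0[i] - 1; // 0 -> -1 unbound
  double p_break = 1.0 - std::exp(-rate_mult * P.c_break * dt);
  double rc2 = bind_cut2(P, rate_mult, dt);
  std::vector<double> f(n * dim);
  std::vector<int> pi_, pj_;

  int n_frames = n_steps / record_every + 1;
  NumericVector times(n_frames);
  NumericMatrix pos(n_frames, n * dim);
  IntegerMatrix partners(n_frames, n);
  int fr = 0;
  times[0] = 0.0;
  for (int k = 0; k < n * dim; ++k) pos(0, k) = x[k];
  for (int i = 0; i < n; ++i) partners(0, i) = part[i] + 1;
  fr = 1;
  for (int step = 1; step <= n_steps; ++step) {
    if (!hybrid_step(x, part, P, dt, rate_mult, p_break, rc2, f, pi_, pj_,
                     freeze_positions))
      stop("non-finite position at step %d; decrease dt", step);
    if (step % record_every == 0 && fr < n_frames) {
      times[fr] = step * dt;
      for (int k = 0; k < n * dim; ++k) pos(fr, k) = x[k];
      for (int i = 0; i < n; ++i) partners(fr, i) = part[i] + 1;
      ++fr;
    }
  }
  return List::create(_["times"] = times, _["positions"] = pos,
                      _["partners"] = partners);
}

// basin classifier for the planar 3-bead system from sorted pairwise
// distances and a collinearity (area) score; label codes:
// 0 transit, 1 unbound-triangle, 2/3/4 two-bead cluster on pair
// (1,2)/(1,3)/(2,3), 5 three-bead cluster, 6 collinear (rearrangement
// saddle crossing: a transition event, not a metastable basin)
static int classify3(const std::vector<double>& x, const NumericVector& thr) {
  const double thr_tri = thr[0], thr_close = thr[1], thr_far = thr[2],
               thr_col = thr[3], thr_col_lo = thr[4], d_unb = thr[5];
  double d12 = std::hypot(x[0] - x[2], x[1] - x[3]);
  double d13 = std::hypot(x[0] - x[4], x[1] - x[5]);
  double d23 = std::hypot(x[2] - x[4], x[3] - x[5]);
  int pair_code = 2; // min pair (1,2)
  if (d13 < d12) { pair_code = 3; }
  if (d23 < std::min(d12, d13)) { pair_code = 4; }
  double dd[3] = {d12, d13, d23};
  std::sort(dd, dd + 3);
  double d1 = dd[0], d2 = dd[1], d3 = dd[2];
  double area = 0.5 * std::fabs((x[2] - x[0]) * (x[5] - x[1]) -
                                (x[3] - x[1]) * (x[4] - x[0]));
  double ascore = d3 > 0 ? area / (d3 * d3) : 0.0;
  if (d1 < thr_close && d2 > thr_far) return pair_code;
  if (ascore < thr_col && d3 > thr_col_lo && d3 < thr_tri) return 6;
  if (d3 < thr_tri) return 5;
  if (std::fabs(d1 - d_unb) < 0.1 * d_unb && std::fabs(d2 - d_unb) < 0.1 * d_unb &&
      std::fabs(d3 - d_unb) < 0.1 * d_unb) return 1;
  return 0;
}

// [[Rcpp::export]]
IntegerVector classify3_cpp(NumericMatrix pos, NumericVector thr) {
  // rows are flattened (x1,y1,x2,y2,x3,y3) configurations
  int m = pos.nrow();
  IntegerVector out(m);
  std::vector<double> x(6);
  for (int r = 0; r < m; ++r) {
    for (int k = 0; k < 6; ++k) x[k] = pos(r, k);
    out[r] = classify3(x, thr);
  }
  return out;
}

// [[Rcpp::export]]
List escape_runs_cpp(NumericMatrix pos0, List par, double dt,
                     double rate_mult, double max_time, int check_every,
                     int dwell, NumericVector thr, int start_label,
                     IntegerVector stop_labels, int n_runs,
                     NumericVector state_probs,
                     IntegerMatrix state_partners) {
  bool stop_ok[7] = {false, false, false, false, false, false, false};
  for (int k = 0; k < stop_labels.size(); ++k)
    if (stop_labels[k] >= 0 && stop_labels[k] <= 6) stop_ok[stop_labels[k]] = true;
  const int n = pos0.nrow(), dim = pos0.ncol();
  if (n != 3 || dim != 2) stop("escape runs are defined for the planar 3-bead model");
  Pars P = read_pars(par, n, dim);
  double p_break = 1.0 - std::exp(-rate_mult * P.c_break * dt);
  double rc2 = bind_cut2(P, rate_mult, dt);
  std::vector<double> f(n * dim), x(n * dim);
  std::vector<int> part(n), pi_, pj_;
  NumericVector times(n_runs);
  IntegerVector labels(n_runs);
  long max_steps = (long)std::ceil(max_time / dt);

  for (int run = 0; run < n_runs; ++run) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < dim; ++k) x[i * dim + k] = pos0(i, k);
    // initial binding state from the local stationary distribution
    double u = unif_rand(), acc = 0.0;
    int s0 = 0;
    for (int s = 0; s < state_probs.size(); ++s) {
      acc += state_probs[s];
      if (u <= acc) { s0 = s; break; }
    }
    for (int i = 0; i < n; ++i) part[i] = state_partners(s0, i) - 1;
    int cand = -1, count = 0;
    double t_cand = 0.0;
    double esc_t = -1.0;
    int esc_lab = -1;
    for (long step = 1; step <= max_steps; ++step) {
      if (!hybrid_step(x, part, P, dt, rate_mult, p_break, rc2, f, pi_, pj_,
                       false))
        stop("non-finite position in escape run %d", run + 1);
      if (step % check_every == 0) {
        int lab = classify3(x, thr);
        if (!stop_ok[lab]) lab = 0; // non-stopping labels act as transit
        if (lab != 0 && lab != start_label) {
          if (lab == 6) { // saddle crossing registers immediately
            esc_t = step * dt; esc_lab = lab; break;
          }
          if (lab == cand) {
            ++count;
          } else {
            cand = lab; count = 1; t_cand = step * dt;
          }
          if (count >= dwell) { esc_t = t_cand; esc_lab = lab; break; }
        } else {
          cand = -1; count = 0;
        }
      }
    }
    if (esc_lab < 0) { times[run] = max_time; labels[run] = -1; }
    else { times[run] = esc_t; labels[run] = esc_lab; }
    if (run % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["labels"] = labels);
}

// exact (Gillespie) jump-chain simulation of a frozen-rate CTMC given its
// generator in the column convention: Q(s, j) is the rate j -> s
// [[Rcpp::export]]
List ctmc_gillespie_cpp(NumericMatrix Q, int s0, int n_events) {
  int ns = Q.nrow();
  IntegerVector states(n_events + 1);
  NumericVector hold(n_events);
  int s = s0 - 1;
  states[0] = s + 1;
  for (int ev = 0; ev < n_events; ++ev) {
    double out = -Q(s, s);
    if (out <= 0) stop("absorbing state reached");
    hold[ev] = exp_rand() / out;
    double u = unif_rand() * out, acc = 0.0;
    int nxt = s;
    for (int k = 0; k < ns; ++k) {
      if (k == s) continue;
      acc += Q(k, s);
      if (u <= acc) { nxt = k; break; }
    }
    s = nxt;
    states[ev + 1] = s + 1;
  }
  return List::create(_["states"] = states, _["holding"] = hold);
}
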