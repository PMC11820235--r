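#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fast inner loop for one trial.
//
// Agent kinds: 0 = q, 1 = q_lambda (linear action values over the noisy
// observation vector, accumulating traces for q_lambda); 2 = sf, 3 = pf
// (successor features learned tabularly from the true state sequence, with
// the noisy observation entering only the value readout psi(o) . w_r used
// for action selection).
//
// Consumes R's RNG (norm_rand / unif_rand) in exactly the same order as the
// pure-R engine in run_episode()/run_trial() so the two paths can be
// cross-checked on identical streams: per episode, d normals for the start
// observation (sigma > 0 only), then per step one uniform for
// explore-vs-greedy, one more uniform when exploring or when the greedy
// argmax is tied, then d normals for the next observation.

namespace {

inline void draw_obs(std::vector<double>& o, int state, int d, double sigma) {
  for (int i = 0; i < d; ++i) o[i] = 0.0;
  o[state] = 1.0;
  if (sigma > 0) {
    for (int i = 0; i < d; ++i) o[i] += sigma * norm_rand();
  }
}

// non-finite values are excluded from the greedy comparison; if none is
// finite the first action is taken (degenerate policy, not an error)
inline int eps_greedy(const std::vector<double>& values, double epsilon) {
  const int n = (int) values.size();
  double u = unif_rand();
  if (u < epsilon) {
    int a = (int) (unif_rand() * n) + 1;
    if (a > n) a = n;
    return a - 1;
  }
  bool any_finite = false;
  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    if (R_finite(values[i]) && (!any_finite || values[i] > mx)) {
      mx = values[i];
      any_finite = true;
    }
  }
  if (!any_finite) return 0;
  std::vector<int> ties;
  for (int i = 0; i < n; ++i)
    if (R_finite(values[i]) && values[i] == mx) ties.push_back(i);
  if (ties.size() == 1) return ties[0];
  int j = (int) (unif_rand() * ties.size()) + 1;
  if (j > (int) ties.size()) j = (int) ties.size();
  return ties[j - 1];
}

inline double dot(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int i = 0; i < d; ++i) s += a[i] * b[i];
  return s;
}

inline int first_finite_argmax(const std::vector<double>& v) {
  int best = 0;
  bool any = false;
  double mx = 0.0;
  for (int i = 0; i < (int) v.size(); ++i) {
    if (R_finite(v[i]) && (!any || v[i] > mx)) {
      mx = v[i];
      best = i;
      any = true;
    }
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
List sim_trial_cpp(int agent_kind, IntegerMatrix next_state, int start,
                   int goal, int step_cap, double sigma, int n_episodes,
                   double alpha, double alpha_w, double alpha_r, double gamma,
                   double lambda, double eps0, double eps_decay,
                   double eps_floor, bool keep_weights) {
  const int d = next_state.nrow();
  const int nA = next_state.ncol();
  const int s0 = start - 1, g = goal - 1;
  const bool is_q = agent_kind == 0 || agent_kind == 1;
  const bool has_trace = agent_kind == 1 || agent_kind == 3;
  const double gl = gamma * lambda;

  // action-value weights (q/q_lambda) and their trace, both nA x d
  std::vector<double> Wq((size_t) nA * d, 0.0), Eq;
  // successor weights (sf/pf): nA matrices d x d (W[i, j]: expected
  // discounted occupancy of feature i after starting in state j), reward
  // weights, eligibility trace over state features, and the cached
  // per-action value table qv[a][j] = sum_i W_a[i, j] * wr[i]
  std::vector<double> Wsf, wr, e, qv;
  if (is_q) {
    if (has_trace) Eq.assign((size_t) nA * d, 0.0);
  } else {
    Wsf.assign((size_t) nA * d * d, 0.0);
    wr.assign(d, 0.0);
    qv.assign((size_t) nA * d, 0.0);
    if (has_trace) e.assign(d, 0.0);
  }

  std::vector<double> o(d), o_next(d), values(nA), delta(d);
  IntegerVector lengths(n_episodes);
  NumericVector rewards(n_episodes);
  double eps = eps0;

  for (int ep = 0; ep < n_episodes; ++ep) {
    if (has_trace) {
      if (is_q) std::fill(Eq.begin(), Eq.end(), 0.0);
      else std::fill(e.begin(), e.end(), 0.0);
    }
    int s = s0, steps = 0;
    draw_obs(o, s, d, sigma);
    for (;;) {
      // action values at the (noisy) percept o
      if (is_q) {
        for (int a = 0; a < nA; ++a)
          values[a] = dot(&Wq[(size_t) a * d], &o[0], d);
      } else {
        for (int a = 0; a < nA; ++a)
          values[a] = dot(&qv[(size_t) a * d], &o[0], d);
      }
      int a = eps_greedy(values, eps);
      int nxt = next_state(s, a) - 1;
      ++steps;
      double r = (nxt == g) ? 1.0 : 0.0;
      bool terminal = nxt == g;
      bool done = terminal || steps >= step_cap;
      draw_obs(o_next, nxt, d, sigma);

      if (is_q) {
        double target = r;
        if (!terminal) {
          // NaN-propagating max, matching R's max() in the reference engine
          double mx = dot(&Wq[0], &o_next[0], d);
          bool any_nan = ISNAN(mx);
          for (int b = 1; b < nA; ++b) {
            double v = dot(&Wq[(size_t) b * d], &o_next[0], d);
            if (ISNAN(v)) any_nan = true;
            else if (v > mx || ISNAN(mx)) mx = v;
          }
          target += gamma * (any_nan ? R_NaN : mx);
        }
        double td = target - dot(&Wq[(size_t) a * d], &o[0], d);
        if (agent_kind == 0) {
          double c = alpha * td;
          double* wa = &Wq[(size_t) a * d];
          for (int j = 0; j < d; ++j) wa[j] += c * o[j];
        } else {
          double* ea = &Eq[(size_t) a * d];
          for (int j = 0; j < d; ++j) ea[j] += o[j];
          double c = alpha * td;
          for (size_t k = 0; k < Wq.size(); ++k) Wq[k] += c * Eq[k];
          for (size_t k = 0; k < Eq.size(); ++k) Eq[k] *= gl;
        }
      } else {
        // tabular feature TD error over true states; greedy next action
        // from the clean value table; terminal state's successor features
        // are its own features
        double* Wa = &Wsf[(size_t) a * d * d];
        if (terminal) {
          for (int i = 0; i < d; ++i)
            delta[i] = (i == s ? 1.0 : 0.0) + gamma * (i == nxt ? 1.0 : 0.0) -
                       Wa[(size_t) i * d + s];
        } else {
          std::vector<double> vnext(nA);
          for (int b = 0; b < nA; ++b) vnext[b] = qv[(size_t) b * d + nxt];
          int astar = first_finite_argmax(vnext);
          const double* Wstar = &Wsf[(size_t) astar * d * d];
          for (int i = 0; i < d; ++i)
            delta[i] = (i == s ? 1.0 : 0.0) +
                       gamma * Wstar[(size_t) i * d + nxt] -
                       Wa[(size_t) i * d + s];
        }
        double dv = alpha_w * dot(&delta[0], &wr[0], d);
        if (agent_kind == 2) {
          for (int i = 0; i < d; ++i) Wa[(size_t) i * d + s] += alpha_w * delta[i];
          qv[(size_t) a * d + s] += dv;
        } else {
          e[s] += 1.0;
          for (int j = 0; j < d; ++j) {
            double ej = e[j];
            if (ej != 0.0) {
              double c = alpha_w * ej;
              for (int i = 0; i < d; ++i) Wa[(size_t) i * d + j] += c * delta[i];
              qv[(size_t) a * d + j] += dv * ej;
            }
          }
        }
        // reward weights learn against the true successor state
        double dw = alpha_r * (r - wr[nxt]);
        if (dw != 0.0) {
          wr[nxt] += dw;
          for (int b = 0; b < nA; ++b) {
            const double* Wb = &Wsf[(size_t) b * d * d + (size_t) nxt * d];
            double* qb = &qv[(size_t) b * d];
            for (int j = 0; j < d; ++j) qb[j] += Wb[j] * dw;
          }
        }
        if (agent_kind == 3) {
          for (int j = 0; j < d; ++j) e[j] *= gl;
        }
      }

      if (done) {
        lengths[ep] = steps;
        rewards[ep] = r;
        break;
      }
      s = nxt;
      std::swap(o, o_next);
    }
    eps = std::max(eps_decay * eps, eps_floor);
  }

  List out = List::create(Named("lengths") = lengths,
                          Named("rewards") = rewards);
  if (keep_weights) {
    if (is_q) {
      NumericMatrix M(nA, d);
      for (int a = 0; a < nA; ++a)
        for (int j = 0; j < d; ++j) M(a, j) = Wq[(size_t) a * d + j];
      out["weights"] = List::create(Named("weights") = M);
    } else {
      List Ws(nA);
      for (int a = 0; a < nA; ++a) {
        NumericMatrix M(d, d);
        for (int i = 0; i < d; ++i)
          for (int j = 0; j < d; ++j)
            M(i, j) = Wsf[(size_t) a * d * d + (size_t) i * d + j];
        Ws[a] = M;
      }
      out["weights"] = List::create(
          Named("W") = Ws,
          Named("w_r") = NumericVector(wr.begin(), wr.end()));
    }
  }
  return out;
}
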