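#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// All randomness comes from R's generator (unif_rand) so that set.seed()
// on the R side fully determines a run, and so that the pure-R reference
// engine can reproduce compiled trajectories draw for draw.  The draw
// protocol (shared with R/rng.R):
//   * integer in 0..n-1: floor(unif_rand() * n), clamped
//   * k-out-of-m sample / shuffle: Fisher-Yates, always consuming a draw
//     even for the trivial last position
static inline int ps_randint(int n) {
  int r = (int) std::floor(unif_rand() * n);
  if (r >= n) r = n - 1;
  if (r < 0) r = 0;
  return r;
}

// Cost bookkeeping: with per-letter net place-value coefficients c_q
// (result minus operands), the signed discrepancy of an assignment d is
// S = sum_q c_q d_q and the cost is |S|, or `penalty` if any leading
// letter holds digit 0.  Swapping slots x,y changes S by
// (c_x - c_y) (d_y - d_x), so every move is O(1).

static inline bool leading_zero(const int *d, const int *lead, int nlead) {
  for (int q = 0; q < nlead; ++q)
    if (d[lead[q]] == 0) return true;
  return false;
}

// Exhaustive enumeration of injective letter->digit maps with early exit.
// Depth-first over letters; leading-zero branches are pruned because they
// carry the penalty cost and can never be solutions.
static void enum_rec(int depth, int L, double partial, const double *coef,
                     const bool *is_lead, bool *used, int *cur,
                     long long limit, long long &count,
                     std::vector<int> *keep, int keep_max) {
  if (count >= limit) return;
  if (depth == L) {
    if (partial == 0.0) {
      ++count;
      if (keep && (int) (keep->size() / L) < keep_max)
        for (int q = 0; q < L; ++q) keep->push_back(cur[q]);
    }
    return;
  }
  for (int dgt = 0; dgt < 10; ++dgt) {
    if (used[dgt]) continue;
    if (dgt == 0 && is_lead[depth]) continue;
    used[dgt] = true;
    cur[depth] = dgt;
    enum_rec(depth + 1, L, partial + coef[depth] * dgt, coef, is_lead, used,
             cur, limit, count, keep, keep_max);
    used[dgt] = false;
    if (count >= limit) return;
  }
}

// [[Rcpp::export]]
double cpp_count_solutions(NumericVector coef, IntegerVector leading, int L,
                           double limit_) {
  long long limit = (limit_ > 4e18) ? (long long) 4e18 : (long long) limit_;
  bool is_lead[10] = {false};
  for (int q = 0; q < leading.size(); ++q) is_lead[leading[q]] = true;
  bool used[10] = {false};
  int cur[10];
  long long count = 0;
  enum_rec(0, L, 0.0, REAL(coef), is_lead, used, cur, limit, count, NULL, 0);
  return (double) count;
}

// [[Rcpp::export]]
IntegerMatrix cpp_find_solutions(NumericVector coef, IntegerVector leading,
                                 int L, int max_count) {
  bool is_lead[10] = {false};
  for (int q = 0; q < leading.size(); ++q) is_lead[leading[q]] = true;
  bool used[10] = {false};
  int cur[10];
  long long count = 0;
  std::vector<int> keep;
  enum_rec(0, L, 0.0, REAL(coef), is_lead, used, cur, (long long) max_count,
           count, &keep, max_count);
  int nsol = (int) (keep.size() / L);
  IntegerMatrix out(nsol, L);
  for (int s = 0; s < nsol; ++s)
    for (int q = 0; q < L; ++q) out(s, q) = keep[(size_t) s * L + q];
  return out;
}

// One complete search: network construction, population initialisation,
// then trials of N asynchronous updates until some agent has cost zero at
// the end of a trial (or max_trials is hit).  RNG draw order per run:
//   1. per agent, K-out-of-(N-1) influencer sample (K draws each)
//   2. per agent, full shuffle of the 10 digit slots (10 draws each)
//   3. per trial: update-order shuffle (N draws), then per agent one
//      Bernoulli draw, then the move's own draws (elementary: 2; global:
//      10; imitation: 1 tie-break draw only when the minimum is tied,
//      plus 1 draw for the copied position unless the update is wasted).
// Agents hold a full 10-slot digit permutation; only the first L slots are
// visible (carry a letter).  Slots L..9 hold the unused digits, which keeps
// the transposition move ergodic over injective maps when L < 10.
// [[Rcpp::export]]
List cpp_run_search(NumericVector coef, IntegerVector leading, double penalty,
                    int L, int N, double p, int K, int global_move,
                    double max_trials_, int record_trace) {
  long long max_trials = (long long) max_trials_;
  const int nlead = leading.size();
  const int *lead = INTEGER(leading);
  const double *cf = REAL(coef);

  // influence networks (fixed for the whole search)
  std::vector<int> net((size_t) N * (K > 0 ? K : 1));
  std::vector<int> others(N > 1 ? N - 1 : 1);
  for (int i = 0; i < N; ++i) {
    int m = 0;
    for (int j = 0; j < N; ++j)
      if (j != i) others[m++] = j;
    for (int t = 0; t < K; ++t) {
      int j = t + ps_randint(m - t);
      std::swap(others[t], others[j]);
      net[(size_t) i * K + t] = others[t];
    }
  }

  // initial population
  std::vector<int> dig((size_t) N * 10);
  std::vector<double> scost(N), cost(N);
  for (int i = 0; i < N; ++i) {
    int *d = &dig[(size_t) i * 10];
    for (int s = 0; s < 10; ++s) d[s] = s;
    for (int s = 0; s < 10; ++s) {
      int j = s + ps_randint(10 - s);
      std::swap(d[s], d[j]);
    }
    double sc = 0;
    for (int q = 0; q < L; ++q) sc += cf[q] * d[q];
    scost[i] = sc;
    cost[i] = leading_zero(d, lead, nlead) ? penalty : std::fabs(sc);
  }

  double prev_min = cost[0];
  for (int i = 1; i < N; ++i)
    if (cost[i] < prev_min) prev_min = cost[i];

  std::vector<double> trace;
  if (record_trace) trace.push_back(prev_min);

  long long t_star = 0, events = 0, wasted = 0, n_imit = 0, n_move = 0;
  bool capped = false;
  std::vector<int> ord(N), ties, Dv;
  ties.reserve(K > 0 ? K : 1);
  Dv.reserve(L);

  for (long long t = 1;; ++t) {
    for (int i = 0; i < N; ++i) ord[i] = i;
    for (int i = 0; i < N; ++i) {
      int j = i + ps_randint(N - i);
      std::swap(ord[i], ord[j]);
    }
    for (int u = 0; u < N; ++u) {
      int a = ord[u];
      int *da = &dig[(size_t) a * 10];
      double un = unif_rand();
      if (un < p) {
        // model string: lowest cached cost among influencers, uniform
        // tie-break in influencer-list order
        const int *infl = &net[(size_t) a * K];
        double best = cost[infl[0]];
        ties.clear();
        ties.push_back(infl[0]);
        for (int q = 1; q < K; ++q) {
          double c = cost[infl[q]];
          if (c < best) {
            best = c;
            ties.clear();
            ties.push_back(infl[q]);
          } else if (c == best) {
            ties.push_back(infl[q]);
          }
        }
        int mi = ties.size() > 1 ? ties[ps_randint((int) ties.size())]
                                 : ties[0];
        const int *dm = &dig[(size_t) mi * 10];
        if (cost[a] < cost[mi]) {
          ++wasted;  // target already cheaper than its model
        } else {
          Dv.clear();
          for (int q = 0; q < L; ++q)
            if (da[q] != dm[q]) Dv.push_back(q);
          if (Dv.empty()) {
            ++wasted;  // identical to the model string
          } else {
            int pos = Dv[ps_randint((int) Dv.size())];
            int dgt = dm[pos];
            int r = 0;
            while (da[r] != dgt) ++r;
            scost[a] += (cf[pos] - cf[r]) * (double) (da[r] - da[pos]);
            std::swap(da[pos], da[r]);
            cost[a] = leading_zero(da, lead, nlead) ? penalty
                                                    : std::fabs(scost[a]);
            ++n_imit;
          }
        }
      } else {
        if (global_move) {
          for (int s = 0; s < 10; ++s) da[s] = s;
          for (int s = 0; s < 10; ++s) {
            int j = s + ps_randint(10 - s);
            std::swap(da[s], da[j]);
          }
          double sc = 0;
          for (int q = 0; q < L; ++q) sc += cf[q] * da[q];
          scost[a] = sc;
        } else {
          int i1 = ps_randint(10);
          int j1 = ps_randint(9);
          if (j1 >= i1) ++j1;
          scost[a] += (cf[i1] - cf[j1]) * (double) (da[j1] - da[i1]);
          std::swap(da[i1], da[j1]);
        }
        cost[a] = leading_zero(da, lead, nlead) ? penalty
                                                : std::fabs(scost[a]);
        ++n_move;
      }
    }
    double mn = cost[0];
    for (int i = 1; i < N; ++i)
      if (cost[i] < mn) mn = cost[i];
    if (record_trace) trace.push_back(mn);
    if (mn != prev_min) ++events;
    prev_min = mn;
    if (mn == 0.0) {
      t_star = t;
      break;
    }
    if (t >= max_trials) {
      t_star = t;
      capped = true;
      break;
    }
    if ((t & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["t_star"] = (double) t_star, _["capped"] = capped,
      _["wasted_updates"] = (double) wasted,
      _["n_change_events"] = (double) events,
      _["n_imitated"] = (double) n_imit, _["n_moved"] = (double) n_move);
  if (record_trace) out["min_trace"] = NumericVector(trace.begin(), trace.end());
  return out;
}
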