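#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Objective over the flattened (A*M) frequency vector q (row (m)*A + a),
// against the reference pref. kind: 0 = chord, 1 = nei_min, 2 = kl.
static double objective(const std::vector<double>& q, const NumericVector& pref,
                        int A, int M, int kind) {
  double s = 0.0;
  if (kind == 2) {                          // Kullback-Leibler, floored
    for (int r = 0; r < A * M; ++r) {
      double p = pref[r];
      if (p > 0.0) {
        double qq = q[r] < 1e-9 ? 1e-9 : q[r];
        s += p * std::log(p / qq);
      }
    }
    return s / M;
  }
  if (kind == 1) {                          // Nei minimum = mean (p-q)^2 / 2
    for (int r = 0; r < A * M; ++r) {
      double d = pref[r] - q[r];
      s += d * d;
    }
    return s / (2.0 * M);
  }
  for (int m = 0; m < M; ++m) {             // Cavalli-Sforza chord
    double h = 0.0;
    for (int a = 0; a < A; ++a) {
      double pq = pref[m * A + a] * q[m * A + a];
      if (pq > 0.0) h += std::sqrt(pq);
    }
    double inner = 2.0 * (1.0 - h);
    if (inner < 0.0) inner = 0.0;
    s += std::sqrt(inner);
  }
  return 2.0 * s / (M_PI * M);
}

static inline int runif_int(int k) {        // uniform on 0..k-1, R RNG
  int r = (int)(unif_rand() * k);
  return r >= k ? k - 1 : r;
}

// Simulated annealing over integer offspring counts per candidate parent.
// Moves transfer one offspring slot between two same-sex parents; counts
// stay within [0, cap] and sum to N per sex. Expected frequencies are
// q = (gM %*% cm + gF %*% cf) / (2N). Uses R's RNG throughout.
// [[Rcpp::export]]
List cpp_sa_optimize(NumericMatrix gM, NumericMatrix gF, NumericVector pref,
                     int A, int M, int N, int cap, int kind,
                     IntegerVector c0m, IntegerVector c0f,
                     double cooling, int moves_per_temp,
                     int stall_temps, int max_temps, int pilot_moves) {
  RNGScope scope;
  const int nm = gM.ncol(), nf = gF.ncol(), R = A * M;
  std::vector<int> cm(c0m.begin(), c0m.end()), cf(c0f.begin(), c0f.end());

  std::vector<double> q(R, 0.0);
  const double w = 0.5 / N;
  for (int i = 0; i < nm; ++i)
    if (cm[i] > 0)
      for (int r = 0; r < R; ++r) q[r] += w * cm[i] * gM(r, i);
  for (int i = 0; i < nf; ++i)
    if (cf[i] > 0)
      for (int r = 0; r < R; ++r) q[r] += w * cf[i] * gF(r, i);

  double e = objective(q, pref, A, M, kind);
  std::vector<int> best_cm = cm, best_cf = cf;
  double best_e = e;

  // Propose a random slot transfer within one sex; fills don/rec and the
  // new q/energy. Returns false when no move is possible.
  std::vector<double> qnew(R);
  int don = -1, rec = -1, sex = 0;
  double enew = 0.0;
  auto propose = [&]() -> bool {
    sex = (unif_rand() < 0.5) ? 0 : 1;
    for (int attempt = 0; attempt < 2; ++attempt, sex = 1 - sex) {
      std::vector<int>& c = (sex == 0) ? cm : cf;
      NumericMatrix& g = (sex == 0) ? gM : gF;
      int k = (int)c.size();
      if (k < 2) continue;
      // donor: uniform among parents with c > 0
      int ndon = 0;
      for (int i = 0; i < k; ++i) if (c[i] > 0) ++ndon;
      if (ndon == 0) continue;
      int pick = runif_int(ndon);
      don = -1;
      for (int i = 0; i < k; ++i) if (c[i] > 0 && pick-- == 0) { don = i; break; }
      // recipient: uniform among other parents below the cap
      int nrec = 0;
      for (int i = 0; i < k; ++i)
        if (i != don && (cap < 0 || c[i] < cap)) ++nrec;
      if (nrec == 0) continue;
      pick = runif_int(nrec);
      rec = -1;
      for (int i = 0; i < k; ++i)
        if (i != don && (cap < 0 || c[i] < cap) && pick-- == 0) { rec = i; break; }
      for (int r = 0; r < R; ++r)
        qnew[r] = q[r] + w * (g(r, rec) - g(r, don));
      enew = objective(qnew, pref, A, M, kind);
      return true;
    }
    return false;
  };

  auto apply = [&]() {
    std::vector<int>& c = (sex == 0) ? cm : cf;
    c[don] -= 1;
    c[rec] += 1;
    q.swap(qnew);
    e = enew;
    if (e < best_e) {
      best_e = e;
      best_cm = cm;
      best_cf = cf;
    }
  };

  // Pilot: probe uphill deltas from the initial plan to set T0 so that a
  // median uphill move is accepted with probability ~1/2.
  double t0 = 0.0;
  {
    std::vector<double> up;
    for (int s = 0; s < pilot_moves; ++s) {
      if (!propose()) break;
      double d = enew - e;
      if (d > 0) up.push_back(d);
    }
    if (!up.empty()) {
      std::nth_element(up.begin(), up.begin() + up.size() / 2, up.end());
      t0 = up[up.size() / 2] / std::log(2.0);
    }
    if (t0 <= 0.0) t0 = 1e-6;
  }

  double T = t0;
  int stall = 0;
  bool movable = true;
  for (int step = 0; step < max_temps && stall < stall_temps && movable;
       ++step) {
    double best_before = best_e;
    for (int s = 0; s < moves_per_temp; ++s) {
      if (!propose()) { movable = false; break; }
      double d = enew - e;
      if (d <= 0.0 || unif_rand() < std::exp(-d / T)) apply();
    }
    stall = (best_e < best_before) ? 0 : stall + 1;
    T *= cooling;
  }

  return List::create(_["cm"] = IntegerVector(best_cm.begin(), best_cm.end()),
                      _["cf"] = IntegerVector(best_cf.begin(), best_cf.end()),
                      _["value"] = best_e);
}
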