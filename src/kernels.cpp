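#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Pedigree recursions.
// sire/dam are 1-based indices into a topologically sorted pedigree
// (parents strictly before offspring); 0 encodes an unknown parent.
// ---------------------------------------------------------------------------

// Tabular (Emik-Terrill) kinship matrix. Founders are unrelated and
// non-inbred; an unknown parent contributes 0 to the recursion.
// [[Rcpp::export(".kinship_tabular_cpp")]]
NumericMatrix kinship_tabular_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree is not topologically sorted at row %d", i + 1);
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += K(s, j);
      if (d >= 0) v += K(d, j);
      v *= 0.5;
      K(i, j) = v;
      K(j, i) = v;
    }
    const double fi = (s >= 0 && d >= 0) ? K(s, d) : 0.0;
    K(i, i) = 0.5 * (1.0 + fi);
  }
  return K;
}

// Equivalent complete generations: EG_i = sum over known parents of
// (1 + EG_parent) / 2.
// [[Rcpp::export(".eg_recursive_cpp")]]
NumericVector eg_recursive_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector eg(n);
  for (int i = 0; i < n; ++i) {
    double v = 0.0;
    if (sire[i] > 0) v += 0.5 * (1.0 + eg[sire[i] - 1]);
    if (dam[i] > 0) v += 0.5 * (1.0 + eg[dam[i] - 1]);
    eg[i] = v;
  }
  return eg;
}

// ---------------------------------------------------------------------------
// Mating-plan optimizer.
//
// Candidates are indexed 0..M-1 (males) and M..M+F-1 (females) into a
// kinship matrix K (diagonal = self-coancestry (1+F)/2) and an EG vector.
// A harem plan is encoded per female: an offspring count cnt[f] >= 0 and,
// when cnt[f] > 0, a single sire sf[f] in 0..M-1.
//
// Objective families (codes):
//   1 F      sum over pair occurrences of C_jk
//   2 dF     sum of dC_jk = 1 - (1-C_jk)^(2/(g_j+g_k))
//   3 mFm    sum of m_j C_jk m_k, m = mean kinship with the mating group
//   4 dmFdm  sum of dm_j dC_jk dm_k, dm = mean kinship increase
//   5 C      sum over unordered distinct offspring pairs of C_lm
//   6 dC     sum of dC_lm with g_l = 1 + (g_sire + g_dam)/2
//   7 mix    p1 * mean(C_jk) + (1-p1) * mean(C_lm)
// Participation (codes): 0 every female >= 1 offspring; 1 every female and
// every male; 2 free.
// ---------------------------------------------------------------------------

static inline double dct(double c, double g) {
  return 1.0 - std::pow(1.0 - c, 1.0 / g);
}

struct PlanProblem {
  int M, F, Nt, family, part;
  double p1;
  bool useT, useO;
  std::vector<double> T;  // M*F parent-pair terms, index j*F + k
  std::vector<double> O;  // (M*F)^2 offspring-pair terms
  double fx(const std::vector<int>& cnt, const std::vector<int>& sf) const {
    double ps = 0.0, os = 0.0;
    if (useT) {
      for (int f = 0; f < F; ++f)
        if (cnt[f] > 0) ps += cnt[f] * T[sf[f] * F + f];
    }
    if (useO) {
      const int MF = M * F;
      for (int f = 0; f < F; ++f) {
        if (cnt[f] == 0) continue;
        const int tf = sf[f] * F + f;
        os += 0.5 * cnt[f] * (cnt[f] - 1) * O[tf * MF + tf];
        for (int g = f + 1; g < F; ++g) {
          if (cnt[g] == 0) continue;
          os += (double)cnt[f] * cnt[g] * O[tf * MF + sf[g] * F + g];
        }
      }
    }
    if (family <= 4) return ps;
    if (family <= 6) return os;
    const double npairs = 0.5 * Nt * (Nt - 1);
    return p1 * ps / Nt + (npairs > 0 ? (1.0 - p1) * os / npairs : 0.0);
  }
};

static PlanProblem build_problem(const NumericMatrix& K,
                                 const NumericVector& eg,
                                 int M, int F, int family, double p1,
                                 int part, int Nt) {
  PlanProblem P;
  P.M = M; P.F = F; P.Nt = Nt; P.family = family; P.part = part; P.p1 = p1;
  P.useT = (family <= 4 || family == 7);
  P.useO = (family >= 5);
  const int nc = M + F;
  const bool need_eg = (family == 2 || family == 4 || family == 6);
  if (need_eg) {
    if (eg.size() != nc) stop("EG vector required for increase-based objectives");
    for (int i = 0; i < nc; ++i)
      if (eg[i] < 0 || NumericVector::is_na(eg[i]))
        stop("EG values must be non-negative and non-missing");
  }
  // mean-kinship (and mean-increase) weights over the whole mating group
  std::vector<double> m(nc, 0.0), dm(nc, 0.0);
  if (family == 3 || family == 4) {
    for (int i = 0; i < nc; ++i) {
      double sm = 0.0, sdm = 0.0;
      for (int j = 0; j < nc; ++j) {
        if (j == i) continue;
        sm += K(i, j);
        if (family == 4) {
          const double g = 0.5 * (eg[i] + eg[j]);
          if (g <= 0) stop("EG sum must be positive for increase-based objectives");
          sdm += dct(K(i, j), g);
        }
      }
      m[i] = sm / (nc - 1);
      dm[i] = sdm / (nc - 1);
    }
  }
  if (P.useT) {
    P.T.assign((size_t)M * F, 0.0);
    for (int j = 0; j < M; ++j)
      for (int k = 0; k < F; ++k) {
        const double c = K(j, M + k);
        double t;
        switch (family) {
        case 2: {
          const double g = 0.5 * (eg[j] + eg[M + k]);
          if (g <= 0) stop("EG sum must be positive for increase-based objectives");
          t = dct(c, g);
          break;
        }
        case 3: t = m[j] * c * m[M + k]; break;
        case 4: {
          const double g = 0.5 * (eg[j] + eg[M + k]);
          if (g <= 0) stop("EG sum must be positive for increase-based objectives");
          t = dm[j] * dct(c, g) * dm[M + k];
          break;
        }
        default: t = c;
        }
        P.T[(size_t)j * F + k] = t;
      }
  }
  if (P.useO) {
    const int MF = M * F;
    P.O.assign((size_t)MF * MF, 0.0);
    for (int t = 0; t < MF; ++t) {
      const int j1 = t / F, k1 = t % F;
      for (int u = t; u < MF; ++u) {
        const int j2 = u / F, k2 = u % F;
        const double c4 = 0.25 * (K(j1, j2) + K(j1, M + k2) +
                                  K(M + k1, j2) + K(M + k1, M + k2));
        double v = c4;
        if (family == 6) {
          const double gl = 1.0 + 0.5 * (eg[j1] + eg[M + k1]);
          const double gm = 1.0 + 0.5 * (eg[j2] + eg[M + k2]);
          v = dct(c4, 0.5 * (gl + gm));
        }
        P.O[(size_t)t * MF + u] = v;
        P.O[(size_t)u * MF + t] = v;
      }
    }
  }
  return P;
}

// Evaluate the objective of an explicit plan (used by objective_value()).
// [[Rcpp::export(".plan_objective_cpp")]]
double plan_objective_cpp(NumericMatrix K, NumericVector eg, int M, int F,
                          int family, double p1, IntegerVector cnt,
                          IntegerVector sf) {
  int Nt = 0;
  for (int f = 0; f < F; ++f) Nt += cnt[f];
  PlanProblem P = build_problem(K, eg, M, F, family, p1, 2, Nt);
  std::vector<int> c(cnt.begin(), cnt.end());
  std::vector<int> s(F, 0);
  for (int f = 0; f < F; ++f) s[f] = (cnt[f] > 0) ? sf[f] - 1 : 0;
  return P.fx(c, s);
}

namespace {

struct BestPlan {
  double fx;
  std::vector<int> cnt, sf;
  long evals;
  bool found;
};

// exhaustive enumeration: lexicographic over (counts, sire assignments),
// first strict improvement kept (deterministic tie-break)
void enum_sires(const PlanProblem& P, std::vector<int>& cnt,
                std::vector<int>& sf, int f, int males_missing,
                std::vector<int>& mu, BestPlan& best) {
  const int F = P.F, M = P.M;
  if (f == F) {
    if (P.part == 1 && males_missing > 0) return;
    const double v = P.fx(cnt, sf);
    ++best.evals;
    if (!best.found || v < best.fx - 1e-12) {
      best.found = true;
      best.fx = v;
      best.cnt = cnt;
      best.sf = sf;
    }
    return;
  }
  if (cnt[f] == 0) {
    sf[f] = 0;
    enum_sires(P, cnt, sf, f + 1, males_missing, mu, best);
    return;
  }
  // prune: remaining active dams must cover the still-unused males
  int active_left = 0;
  for (int g = f; g < P.F; ++g) active_left += (cnt[g] > 0);
  if (P.part == 1 && males_missing > active_left) return;
  for (int j = 0; j < M; ++j) {
    sf[f] = j;
    const int miss = males_missing - (mu[j] == 0 ? 1 : 0);
    ++mu[j];
    enum_sires(P, cnt, sf, f + 1, miss, mu, best);
    --mu[j];
  }
}

void enum_counts(const PlanProblem& P, std::vector<int>& cnt, int f,
                 int left, int floor_f, BestPlan& best) {
  const int F = P.F;
  if (f == F - 1) {
    if (left < floor_f) return;
    cnt[f] = left;
    std::vector<int> sf(F, 0), mu(P.M, 0);
    enum_sires(P, cnt, sf, 0, P.M, mu, best);
    return;
  }
  const int remaining_floors = floor_f * (F - 1 - f);
  for (int c = floor_f; c <= left - remaining_floors; ++c) {
    cnt[f] = c;
    enum_counts(P, cnt, f + 1, left - c, floor_f, best);
  }
}

inline int rint_below(int k) {
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// greedy first-improvement descent over the move neighbourhood
void descend(const PlanProblem& P, std::vector<int>& cnt, std::vector<int>& sf,
             std::vector<int>& mu, double& cur) {
  const int F = P.F, M = P.M;
  const int floor_f = (P.part == 2) ? 0 : 1;
  bool improved = true;
  int sweeps = 0;
  while (improved && ++sweeps <= 200) {
    improved = false;
    for (int f = 0; f < F; ++f) {  // reassign a dam's sire
      if (cnt[f] == 0) continue;
      const int a = sf[f];
      for (int b = 0; b < M; ++b) {
        if (b == a) continue;
        if (P.part == 1 && mu[a] == 1) continue;
        sf[f] = b; --mu[a]; ++mu[b];
        const double v = P.fx(cnt, sf);
        if (v < cur - 1e-12) { cur = v; improved = true; break; }
        sf[f] = a; ++mu[a]; --mu[b];
      }
    }
    for (int f = 0; f < F; ++f) {  // move one offspring slot between dams
      if (cnt[f] <= floor_f) continue;
      for (int g = 0; g < F; ++g) {
        if (g == f) continue;
        const bool deact = (cnt[f] == 1);
        if (deact && P.part == 1 && mu[sf[f]] == 1) continue;
        if (cnt[g] > 0) {
          --cnt[f]; ++cnt[g];
          if (deact) --mu[sf[f]];
          const double v = P.fx(cnt, sf);
          if (v < cur - 1e-12) { cur = v; improved = true; break; }
          if (deact) ++mu[sf[f]];
          ++cnt[f]; --cnt[g];
        } else {
          bool done = false;
          for (int b = 0; b < M && !done; ++b) {  // activate dam g with sire b
            --cnt[f]; ++cnt[g]; sf[g] = b; ++mu[b];
            if (deact) --mu[sf[f]];
            const double v = P.fx(cnt, sf);
            if (v < cur - 1e-12) { cur = v; improved = true; done = true; break; }
            if (deact) ++mu[sf[f]];
            ++cnt[f]; --cnt[g]; --mu[b];
          }
          if (done) break;
        }
      }
    }
    for (int f = 0; f < F; ++f) {  // swap sires between two dams
      if (cnt[f] == 0) continue;
      for (int g = f + 1; g < F; ++g) {
        if (cnt[g] == 0 || sf[f] == sf[g]) continue;
        std::swap(sf[f], sf[g]);
        const double v = P.fx(cnt, sf);
        if (v < cur - 1e-12) { cur = v; improved = true; break; }
        std::swap(sf[f], sf[g]);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(".optimize_plan_cpp")]]
List optimize_plan_cpp(NumericMatrix K, NumericVector eg, int M, int F,
                       int family, double p1, int part, int Nt,
                       std::string method, int n_restarts, int n_iter) {
  if (M < 1 || F < 1) stop("need at least one candidate of each sex");
  if (M > F) stop("infeasible: more males than females (harem constraint)");
  const int floor_f = (part == 2) ? 0 : 1;
  if (Nt < floor_f * F)
    stop("infeasible: cohort size %d below the participation floor %d",
         Nt, floor_f * F);
  if (part == 1 && M > F)
    stop("infeasible: every male must contribute but males exceed females");
  if (Nt < 1) stop("cohort size must be positive");

  PlanProblem P = build_problem(K, eg, M, F, family, p1, part, Nt);
  BestPlan best;
  best.found = false; best.fx = R_PosInf; best.evals = 0;

  if (method == "exact") {
    std::vector<int> cnt(F, 0);
    enum_counts(P, cnt, 0, Nt, floor_f, best);
    if (!best.found) stop("infeasible: no plan satisfies the constraints");
  } else {  // simulated annealing + descent, best over restarts
    RNGScope scope;
    for (int r = 0; r < n_restarts; ++r) {
      std::vector<int> cnt(F, floor_f), sf(F, 0), mu(M, 0);
      int placed = floor_f * F;
      while (placed < Nt) { ++cnt[rint_below(F)]; ++placed; }
      if (part == 2) {
        // ensure at least one active dam
        bool any = false;
        for (int f = 0; f < F; ++f) any = any || cnt[f] > 0;
        if (!any) ++cnt[rint_below(F)];
      }
      // initial sires: for part==1 cover every male first
      std::vector<int> active;
      for (int f = 0; f < F; ++f) if (cnt[f] > 0) active.push_back(f);
      for (size_t a = active.size(); a > 1; --a)
        std::swap(active[a - 1], active[rint_below((int)a)]);
      for (size_t i = 0; i < active.size(); ++i) {
        const int f = active[i];
        const int j = (part == 1 && (int)i < M) ? (int)i : rint_below(M);
        sf[f] = j; ++mu[j];
      }
      double cur = P.fx(cnt, sf);
      double bfx = cur;
      std::vector<int> bcnt = cnt, bsf = sf;
      // temperature from sampled move deltas
      double T0 = 1e-3;
      {
        double mx = 0.0;
        for (int s = 0; s < 30; ++s) {
          const int f = active[rint_below((int)active.size())];
          const int a = sf[f], b = rint_below(M);
          if (b == a) continue;
          sf[f] = b;
          mx = std::max(mx, std::fabs(P.fx(cnt, sf) - cur));
          sf[f] = a;
        }
        T0 = std::max(1e-3, mx);
      }
      const double alpha = std::pow(1e-4, 1.0 / std::max(1, n_iter));
      double temp = T0;
      // moves applied in place; `undo` encodes how to revert a rejection
      for (int it = 0; it < n_iter; ++it, temp *= alpha) {
        const double u = unif_rand();
        int mtype = -1, uf = -1, ug = -1, ua = -1, ub = -1;
        if (u < 0.4) {  // reassign a random active dam's sire
          int f = rint_below(F);
          for (int k = 0; k < F && cnt[f] == 0; ++k) f = (f + 1) % F;
          if (cnt[f] > 0) {
            const int a = sf[f], b = rint_below(M);
            if (b != a && !(P.part == 1 && mu[a] == 1)) {
              sf[f] = b; --mu[a]; ++mu[b];
              mtype = 0; uf = f; ua = a; ub = b;
            }
          }
        } else if (u < 0.8) {  // move a slot between dams
          int f = rint_below(F);
          for (int k = 0; k < F && cnt[f] <= floor_f; ++k) f = (f + 1) % F;
          if (cnt[f] > floor_f) {
            int g = rint_below(F);
            if (g != f) {
              const bool deact = (cnt[f] == 1);
              if (!(deact && P.part == 1 && mu[sf[f]] == 1)) {
                --cnt[f]; ++cnt[g];
                if (deact) --mu[sf[f]];
                ub = -1;
                if (cnt[g] == 1) { sf[g] = rint_below(M); ++mu[sf[g]]; ub = sf[g]; }
                mtype = 1; uf = f; ug = g; ua = deact ? sf[f] : -1;
              }
            }
          }
        } else {  // swap sires of two active dams
          int f = rint_below(F), g = rint_below(F);
          for (int k = 0; k < F && cnt[f] == 0; ++k) f = (f + 1) % F;
          for (int k = 0; k < F && (cnt[g] == 0 || g == f); ++k) g = (g + 1) % F;
          if (cnt[f] > 0 && cnt[g] > 0 && g != f && sf[f] != sf[g]) {
            std::swap(sf[f], sf[g]);
            mtype = 2; uf = f; ug = g;
          }
        }
        if (mtype < 0) continue;
        const double v = P.fx(cnt, sf);
        ++best.evals;
        if (v < cur || unif_rand() < std::exp(-(v - cur) / temp)) {
          cur = v;
          if (cur < bfx - 1e-12) { bfx = cur; bcnt = cnt; bsf = sf; }
        } else {  // revert
          if (mtype == 0) {
            sf[uf] = ua; ++mu[ua]; --mu[ub];
          } else if (mtype == 1) {
            if (ub >= 0) --mu[ub];
            ++cnt[uf]; --cnt[ug];
            if (ua >= 0) ++mu[ua];
          } else {
            std::swap(sf[uf], sf[ug]);
          }
        }
      }
      // polish the best state of this restart to a local optimum
      cnt = bcnt; sf = bsf;
      std::fill(mu.begin(), mu.end(), 0);
      for (int f = 0; f < F; ++f) if (cnt[f] > 0) ++mu[sf[f]];
      double cur2 = bfx;
      descend(P, cnt, sf, mu, cur2);
      if (!best.found || cur2 < best.fx - 1e-12) {
        best.found = true; best.fx = cur2; best.cnt = cnt; best.sf = sf;
      }
    }
  }
  IntegerVector cnt_out(F), sf_out(F);
  for (int f = 0; f < F; ++f) {
    cnt_out[f] = best.cnt[f];
    sf_out[f] = best.cnt[f] > 0 ? best.sf[f] + 1 : NA_INTEGER;
  }
  return List::create(_["fx"] = best.fx, _["count"] = cnt_out,
                      _["sire"] = sf_out, _["evals"] = (double)best.evals);
}

// Upper bound on the exact enumeration size, used to pick a method.
// [[Rcpp::export(".plan_space_bound_cpp")]]
double plan_space_bound_cpp(int M, int F, int Nt, int part) {
  const int floor_f = (part == 2) ? 0 : 1;
  const int left = Nt - floor_f * F;
  if (left < 0) return 0.0;
  // compositions of `left` over F slots
  double comps = 1.0;
  for (int i = 1; i < F; ++i) comps *= (double)(left + i) / i;
  const int amax = std::min(F, floor_f > 0 ? F : Nt);
  double sires = 1.0;
  for (int a = 0; a < amax; ++a) {
    sires *= M;
    if (comps * sires > 1e15) return 1e15;
  }
  return comps * sires;
}
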