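// Simplified Zuker-style minimum-free-energy folder for single-stranded RNA.
//
// Energy model: Watson-Crick pairs only; dinucleotide stack increments shared
// with the duplex thermodynamics module; logarithmic hairpin / bulge /
// internal loop penalties; linear multiloop model. No dangles, no coaxial
// stacking, no special loops. Deterministic traceback with a documented
// checking order (external: leftmost pairable position, smallest partner;
// paired spans: interior candidates in (k, l) ascending order, then
// multiloop splits, then hairpin).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-7;

static inline bool can_pair(int a, int b) {
  // 0=A 1=C 2=G 3=U
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1);
}

struct EnergyModel {
  std::vector<double> stack; // 16, index a*4+b for top-strand step a,b
  double hairpin_base, hairpin_ref;
  double bulge_base, bulge_ref;
  double internal_base, internal_ref, internal_asym, internal_asym_max;
  double log_coef;
  double ml_close, ml_branch, ml_unpaired;
  int max_loop;
  int min_hairpin;

  double hairpinE(int u) const {
    return hairpin_base + log_coef * std::log((double)u / hairpin_ref);
  }
  double bulgeE(int u) const {
    return bulge_base + log_coef * std::log((double)u / bulge_ref);
  }
  double internalE(int u1, int u2) const {
    double asym = internal_asym * std::abs(u1 - u2);
    if (asym > internal_asym_max) asym = internal_asym_max;
    return internal_base + log_coef * std::log((double)(u1 + u2) / internal_ref) + asym;
  }
};

class Folder {
public:
  Folder(const std::vector<int>& s, const EnergyModel& em)
    : seq(s), em(em), n((int)s.size()),
      V(n, std::vector<double>(n, INF)),
      WM(n, std::vector<double>(n, INF)),
      E(n + 1, 0.0), pairv(n, -1) {}

  void run() {
    fill();
    external();
    traceback();
  }

  double mfe() const { return E[0]; }
  std::string dotbracket() const {
    std::string db(n, '.');
    for (int i = 0; i < n; ++i) {
      if (pairv[i] > i) { db[i] = '('; db[pairv[i]] = ')'; }
      else if (pairv[i] >= 0 && pairv[i] < i) db[i] = ')';
    }
    return db;
  }

private:
  std::vector<int> seq;
  EnergyModel em;
  int n;
  std::vector< std::vector<double> > V, WM;
  std::vector<double> E; // suffix minima, E[i] = MFE of s[i..n-1], E[n]=0
  std::vector<int> pairv;

  double interiorE(int i, int j, int k, int l) const {
    int u1 = k - i - 1, u2 = j - l - 1;
    if (u1 == 0 && u2 == 0) return em.stack[seq[i] * 4 + seq[i + 1]];
    if (u1 == 0 || u2 == 0) return em.bulgeE(u1 + u2);
    return em.internalE(u1, u2);
  }

  void fill() {
    for (int len = 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        // --- V(i, j): i paired with j ---
        if (len >= em.min_hairpin + 2 && can_pair(seq[i], seq[j])) {
          double best = em.hairpinE(len - 2);
          // interior loops (includes stacks and bulges)
          for (int k = i + 1; k < j; ++k) {
            int u1 = k - i - 1;
            if (u1 > em.max_loop) break;
            for (int l = j - 1; l > k; --l) {
              int u2 = j - l - 1;
              if (u1 + u2 > em.max_loop) break;
              if (V[k][l] >= INF / 2) continue;
              double e = interiorE(i, j, k, l) + V[k][l];
              if (e < best) best = e;
            }
          }
          // multiloop: split the interior into two WM segments
          for (int k = i + 2; k <= j - 1; ++k) {
            if (WM[i + 1][k - 1] >= INF / 2 || WM[k][j - 1] >= INF / 2) continue;
            double e = em.ml_close + em.ml_branch +
                       WM[i + 1][k - 1] + WM[k][j - 1];
            if (e < best) best = e;
          }
          V[i][j] = best;
        }
        // --- WM(i, j): >=1 branch inside a multiloop ---
        double w = INF;
        if (V[i][j] < INF / 2) w = V[i][j] + em.ml_branch;
        if (len > 1) {
          if (WM[i][j - 1] < INF / 2) w = std::min(w, WM[i][j - 1] + em.ml_unpaired);
          if (WM[i + 1][j] < INF / 2) w = std::min(w, WM[i + 1][j] + em.ml_unpaired);
          for (int k = i + 1; k <= j; ++k) {
            if (WM[i][k - 1] >= INF / 2 || WM[k][j] >= INF / 2) continue;
            w = std::min(w, WM[i][k - 1] + WM[k][j]);
          }
        }
        WM[i][j] = w;
      }
    }
  }

  void external() {
    E[n] = 0.0;
    for (int i = n - 1; i >= 0; --i) {
      double best = E[i + 1]; // i unpaired, no cost in the exterior loop
      for (int j = i + 1; j < n; ++j) {
        if (V[i][j] >= INF / 2) continue;
        double e = V[i][j] + E[j + 1];
        if (e < best) best = e;
      }
      E[i] = best;
    }
  }

  void trace_v(int i, int j);
  void trace_wm(int i, int j);

  void traceback() {
    int i = 0;
    while (i < n) {
      bool paired = false;
      for (int j = i + 1; j < n; ++j) {
        if (V[i][j] >= INF / 2) continue;
        if (std::fabs(V[i][j] + E[j + 1] - E[i]) < EPS) {
          trace_v(i, j);
          i = j + 1;
          paired = true;
          break;
        }
      }
      if (!paired) ++i;
    }
  }
};

void Folder::trace_v(int i, int j) {
  pairv[i] = j; pairv[j] = i;
  double target = V[i][j];
  // interior candidates, (k, l) ascending in k then descending loop size
  for (int k = i + 1; k < j; ++k) {
    int u1 = k - i - 1;
    if (u1 > em.max_loop) break;
    for (int l = j - 1; l > k; --l) {
      int u2 = j - l - 1;
      if (u1 + u2 > em.max_loop) break;
      if (V[k][l] >= INF / 2) continue;
      if (std::fabs(interiorE(i, j, k, l) + V[k][l] - target) < EPS) {
        trace_v(k, l);
        return;
      }
    }
  }
  for (int k = i + 2; k <= j - 1; ++k) {
    if (WM[i + 1][k - 1] >= INF / 2 || WM[k][j - 1] >= INF / 2) continue;
    if (std::fabs(em.ml_close + em.ml_branch + WM[i + 1][k - 1] + WM[k][j - 1]
                  - target) < EPS) {
      trace_wm(i + 1, k - 1);
      trace_wm(k, j - 1);
      return;
    }
  }
  // hairpin: nothing further to trace
}

void Folder::trace_wm(int i, int j) {
  double target = WM[i][j];
  if (V[i][j] < INF / 2 && std::fabs(V[i][j] + em.ml_branch - target) < EPS) {
    trace_v(i, j);
    return;
  }
  if (j > i) {
    if (WM[i][j - 1] < INF / 2 &&
        std::fabs(WM[i][j - 1] + em.ml_unpaired - target) < EPS) {
      trace_wm(i, j - 1);
      return;
    }
    if (WM[i + 1][j] < INF / 2 &&
        std::fabs(WM[i + 1][j] + em.ml_unpaired - target) < EPS) {
      trace_wm(i + 1, j);
      return;
    }
    for (int k = i + 1; k <= j; ++k) {
      if (WM[i][k - 1] >= INF / 2 || WM[k][j] >= INF / 2) continue;
      if (std::fabs(WM[i][k - 1] + WM[k][j] - target) < EPS) {
        trace_wm(i, k - 1);
        trace_wm(k, j);
        return;
      }
    }
  }
  Rcpp::stop("internal error: WM traceback failed");
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq_codes, NumericVector stack16,
                  List loop_params, int min_hairpin) {
  EnergyModel em;
  em.stack.assign(stack16.begin(), stack16.end());
  if ((int)em.stack.size() != 16) stop("stack table must have 16 entries");
  em.hairpin_base = as<double>(loop_params["hairpin_base"]);
  em.hairpin_ref = as<double>(loop_params["hairpin_ref"]);
  em.bulge_base = as<double>(loop_params["bulge_base"]);
  em.bulge_ref = as<double>(loop_params["bulge_ref"]);
  em.internal_base = as<double>(loop_params["internal_base"]);
  em.internal_ref = as<double>(loop_params["internal_ref"]);
  em.internal_asym = as<double>(loop_params["internal_asym"]);
  em.internal_asym_max = as<double>(loop_params["internal_asym_max"]);
  em.log_coef = as<double>(loop_params["log_coef"]);
  em.ml_close = as<double>(loop_params["ml_close"]);
  em.ml_branch = as<double>(loop_params["ml_branch"]);
  em.ml_unpaired = as<double>(loop_params["ml_unpaired"]);
  em.max_loop = as<int>(loop_params["max_loop"]);
  em.min_hairpin = min_hairpin;

  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] < 0 || s[i] > 3) stop("sequence codes must be in 0..3");
  }
  Folder f(s, em);
  f.run();
  return List::create(_["mfe"] = f.mfe(), _["structure"] = f.dotbracket());
}
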