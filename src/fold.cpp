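// Zuker-style minimum-free-energy folding under the package's simplified
// nearest-neighbor model, with optional per-nucleotide SHAPE pseudo-energies
// charged on helix stacks. Nested structures only; the pseudoknot heuristic
// drives this routine from R with masked positions.
//
// Tie-breaking: energies equal within EPS prefer fewer pairs; remaining ties
// fall to a fixed candidate evaluation order (hairpin, then interior loops by
// ascending 5' inner index and descending 3' inner index, then multibranch
// splits by ascending split point), which makes the traceback deterministic.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-9;

static inline bool better(double e1, int n1, double e2, int n2) {
  if (e1 < e2 - EPS) return true;
  if (e1 <= e2 + EPS && n1 < n2) return true;
  return false;
}

struct Cell { double e; int n; int act; int a1; int a2; };

class Folder {
public:
  int n, minh, max_internal;
  std::vector<int> code;          // A=0 C=1 G=2 U=3 N=4
  std::vector<bool> masked;
  std::vector<double> dg;         // per-nt SHAPE pseudo-energy
  bool dc;                        // double-charge convention
  double stack[3][3];
  double hairpin_base, bulge_base, internal_base, loop_log_coef;
  double mb_offset, mb_branch, mb_unpaired;

  std::vector<Cell> V, M, Mb;
  std::vector<double> W; std::vector<int> nW, actW;

  int cls(int a, int b) const {
    // 0=GC 1=AU 2=GU, -1 = not pairable
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 0;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 2;
    return -1;
  }
  bool pairOK(int i, int j) const {
    return !masked[i] && !masked[j] && (j - i) > minh &&
           cls(code[i], code[j]) >= 0;
  }
  double hp(int l) const { return hairpin_base + loop_log_coef * std::log(l / 3.0); }
  double bg(int l) const { return bulge_base + loop_log_coef * std::log((double)l); }
  double il(int s) const { return internal_base + loop_log_coef * std::log(s / 2.0); }
  double stackCharge(int i, int j, int k, int l) const {
    double s = stack[cls(code[i], code[j])][cls(code[k], code[l])];
    s += dg[i] + dg[j];
    if (dc) s += dg[k] + dg[l];
    return s;
  }

  inline Cell &at(std::vector<Cell> &A, int i, int j) { return A[i * n + j]; }

  void fill() {
    Cell inf = {INF, 0, -1, -1, -1};
    V.assign((size_t)n * n, inf);
    M.assign((size_t)n * n, inf);
    Mb.assign((size_t)n * n, inf);
    for (int len = 1; len < n; ++len) {
      for (int i = 0; i + len < n; ++i) {
        int j = i + len;
        // ---- V(i,j)
        if (len > minh && pairOK(i, j)) {
          Cell best = {hp(j - i - 1), 1, 0, -1, -1};
          for (int k = i + 1; k < j; ++k) {
            int l1 = k - i - 1;
            if (l1 > max_internal) break;
            for (int l = j - 1; l > k; --l) {
              int l2 = j - l - 1;
              if (l1 + l2 > max_internal) break;
              Cell &in = at(V, k, l);
              if (in.e >= INF) continue;
              double cost;
              if (l1 == 0 && l2 == 0) cost = stackCharge(i, j, k, l);
              else if (l1 == 0 || l2 == 0) cost = bg(l1 + l2);
              else cost = il(l1 + l2);
              double e = cost + in.e; int m = 1 + in.n;
              if (better(e, m, best.e, best.n)) best = {e, m, 1, k, l};
            }
          }
          for (int k = i + 2; k <= j - 2; ++k) {
            Cell &a = at(M, i + 1, k - 1);
            Cell &b = at(Mb, k, j - 1);
            if (a.e >= INF || b.e >= INF) continue;
            double e = mb_offset + mb_branch + a.e + b.e;
            int m = 1 + a.n + b.n;
            if (better(e, m, best.e, best.n)) best = {e, m, 2, k, -1};
          }
          at(V, i, j) = best;
        }
        // ---- Mb(i,j): one branch starting exactly at i, trailing unpaired
        {
          Cell best = inf;
          Cell &v = at(V, i, j);
          if (v.e < INF) best = {v.e + mb_branch, v.n, 0, -1, -1};
          if (j > i) {
            Cell &p = at(Mb, i, j - 1);
            if (p.e < INF && better(p.e + mb_unpaired, p.n, best.e, best.n))
              best = {p.e + mb_unpaired, p.n, 1, -1, -1};
          }
          at(Mb, i, j) = best;
        }
        // ---- M(i,j): >= 1 branch
        {
          Cell best = inf;
          Cell &b0 = at(Mb, i, j);
          if (b0.e < INF) best = {b0.e, b0.n, 0, -1, -1};
          Cell &lu = at(M, i + 1, j);
          if (i + 1 <= j && lu.e < INF &&
              better(lu.e + mb_unpaired, lu.n, best.e, best.n))
            best = {lu.e + mb_unpaired, lu.n, 1, -1, -1};
          for (int k = i + 1; k <= j; ++k) {
            Cell &a = at(M, i, k - 1);
            Cell &b = at(Mb, k, j);
            if (a.e >= INF || b.e >= INF) continue;
            double e = a.e + b.e; int m = a.n + b.n;
            if (better(e, m, best.e, best.n)) best = {e, m, 2, k, -1};
          }
          at(M, i, j) = best;
        }
      }
    }
    // ---- exterior W over prefixes (1-based j)
    W.assign(n + 1, 0.0); nW.assign(n + 1, 0); actW.assign(n + 1, 0);
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1]; nW[j] = nW[j - 1]; actW[j] = 0;
      for (int i = 1; i <= j; ++i) {
        Cell &v = at(V, i - 1, j - 1);
        if (v.e >= INF) continue;
        double e = W[i - 1] + v.e; int m = nW[i - 1] + v.n;
        if (better(e, m, W[j], nW[j])) { W[j] = e; nW[j] = m; actW[j] = i; }
      }
    }
  }

  void traceback(std::vector<std::pair<int,int>> &pairs) {
    // entries: (type, i, j) with type 0=V 1=M 2=Mb
    std::vector<std::array<int,3>> st;
    int j = n;
    while (j > 0) {
      if (actW[j] == 0) { --j; continue; }
      int i = actW[j];
      st.push_back({0, i - 1, j - 1});
      j = i - 1;
    }
    while (!st.empty()) {
      auto fr = st.back(); st.pop_back();
      int t = fr[0], i = fr[1], jj = fr[2];
      if (t == 0) {
        Cell &c = at(V, i, jj);
        pairs.push_back({i + 1, jj + 1});
        if (c.act == 1) st.push_back({0, c.a1, c.a2});
        else if (c.act == 2) {
          st.push_back({1, i + 1, c.a1 - 1});
          st.push_back({2, c.a1, jj - 1});
        }
      } else if (t == 1) {
        Cell &c = at(M, i, jj);
        if (c.act == 0) st.push_back({2, i, jj});
        else if (c.act == 1) st.push_back({1, i + 1, jj});
        else { st.push_back({1, i, c.a1 - 1}); st.push_back({2, c.a1, jj}); }
      } else {
        Cell &c = at(Mb, i, jj);
        if (c.act == 0) st.push_back({0, i, jj});
        else st.push_back({2, i, jj - 1});
      }
    }
  }
};

// [[Rcpp::export(name = ".fold_nested_cpp")]]
List fold_nested_cpp(IntegerVector seqcode, NumericVector dg,
                     LogicalVector masked, List model, bool double_charge) {
  Folder f;
  f.n = seqcode.size();
  if (f.n == 0)
    return List::create(_["energy"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2));
  f.code.assign(seqcode.begin(), seqcode.end());
  f.dg.assign(dg.begin(), dg.end());
  f.masked.resize(f.n);
  for (int i = 0; i < f.n; ++i) f.masked[i] = masked[i];
  f.dc = double_charge;
  NumericMatrix st = model["stack"];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) f.stack[a][b] = st(a, b);
  f.hairpin_base = as<double>(model["hairpin_base"]);
  f.bulge_base = as<double>(model["bulge_base"]);
  f.internal_base = as<double>(model["internal_base"]);
  f.loop_log_coef = as<double>(model["loop_log_coef"]);
  f.mb_offset = as<double>(model["mb_offset"]);
  f.mb_branch = as<double>(model["mb_branch"]);
  f.mb_unpaired = as<double>(model["mb_unpaired"]);
  f.minh = as<int>(model["min_hairpin"]);
  f.max_internal = as<int>(model["max_internal"]);

  f.fill();
  std::vector<std::pair<int,int>> pairs;
  f.traceback(pairs);
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(_["energy"] = f.W[f.n], _["pairs"] = pm);
}
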