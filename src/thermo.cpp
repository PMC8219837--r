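// Nearest-neighbor secondary-structure thermodynamics for short RNAs.
//
// Energy decomposition (shared by energy evaluation, the partition function
// and the MFE recursions): hairpin / stack / bulge / internal-loop terms by
// loop size, affine multiloops (closing + per-branch + per-unpaired), free
// exterior bases. Minimum hairpin loop = 3; lonely pairs allowed; no
// dangling ends or coaxial stacks. All energies kcal/mol.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF_E = 1e9;

struct EPar {
  double stack[7][7];            // indexed by pair types 1..6
  std::vector<double> hairpin;   // by loop size; [0..2] unused
  std::vector<double> internal_; // by total size >= 2
  std::vector<double> bulge;     // by size >= 1
  double asym, asym_max;
  double ml_close, ml_branch, ml_unpaired;
  double lxc;
  int maxloop;
};

// base codes: A=0 C=1 G=2 U=3; pair types 1..6 in order AU CG GC GU UA UG
static int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

static EPar make_par(const List& par) {
  EPar P;
  NumericMatrix st = par["stack"];
  for (int i = 1; i <= 6; i++)
    for (int j = 1; j <= 6; j++) P.stack[i][j] = st(i - 1, j - 1);
  NumericVector hp = par["hairpin"], il = par["internal"], bu = par["bulge"];
  P.hairpin.assign(hp.size() + 3, INF_E);
  for (int i = 0; i < hp.size(); i++) P.hairpin[i + 3] = hp[i];
  P.internal_.assign(il.size() + 2, INF_E);
  for (int i = 0; i < il.size(); i++) P.internal_[i + 2] = il[i];
  P.bulge.assign(bu.size() + 1, INF_E);
  for (int i = 0; i < bu.size(); i++) P.bulge[i + 1] = bu[i];
  P.asym = as<double>(par["asym"]);
  P.asym_max = as<double>(par["asym_max"]);
  P.ml_close = as<double>(par["ml_closing"]);
  P.ml_branch = as<double>(par["ml_branch"]);
  P.ml_unpaired = as<double>(par["ml_unpaired"]);
  P.lxc = as<double>(par["lxc"]);
  P.maxloop = as<int>(par["maxloop"]);
  return P;
}

static double loop_tab(const std::vector<double>& tab, int size, double lxc,
                       int minsize) {
  int mx = (int)tab.size() - 1;
  if (size < minsize) return INF_E;
  if (size <= mx) return tab[size];
  return tab[mx] + lxc * std::log((double)size / mx);
}

static double hairpin_E(int i, int j, const EPar& P) {
  return loop_tab(P.hairpin, j - i - 1, P.lxc, 3);
}

// loop closed by (i,j) with interior pair (k,l)
static double two_loop_E(int i, int j, int k, int l,
                         const std::vector<int>& s, const EPar& P) {
  int n1 = k - i - 1, n2 = j - l - 1;
  if (n1 == 0 && n2 == 0)
    return P.stack[pair_type(s[i], s[j])][pair_type(s[k], s[l])];
  if (n1 == 0 || n2 == 0) return loop_tab(P.bulge, n1 + n2, P.lxc, 1);
  return loop_tab(P.internal_, n1 + n2, P.lxc, 2) +
         std::min(P.asym_max, P.asym * std::abs(n1 - n2));
}

// --- energy of a given structure ------------------------------------------

// ptab: 1-based partner indices (0 = unpaired), as an R integer vector.
// Returns NA_real_ if any pair is not in the allowed set; the offending
// pair is reported through `bad` (1-based i, j, or 0s).
// [[Rcpp::export]]
List c_energy(IntegerVector codes, IntegerVector ptab, List par) {
  EPar P = make_par(par);
  int n = codes.size();
  std::vector<int> s(codes.begin(), codes.end());
  std::vector<int> pt(n + 1, 0);
  for (int i = 1; i <= n; i++) pt[i] = ptab[i - 1];
  for (int i = 1; i <= n; i++) {
    if (pt[i] > i && !pair_type(s[i - 1], s[pt[i] - 1]))
      return List::create(_["energy"] = NA_REAL, _["bad_i"] = i,
                          _["bad_j"] = pt[i]);
  }
  double E = 0.0;
  for (int i = 1; i <= n; i++) {
    int j = pt[i];
    if (j <= i) continue;
    // classify the loop closed by (i,j): walk direct children
    int k = i + 1, nchild = 0, unp = 0, c1 = 0, c2 = 0;
    while (k < j) {
      if (pt[k] > k) {
        if (++nchild == 1) { c1 = k; c2 = pt[k]; }
        k = pt[k] + 1;
      } else { unp++; k++; }
    }
    if (nchild == 0) E += hairpin_E(i - 1, j - 1, P);
    else if (nchild == 1) E += two_loop_E(i - 1, j - 1, c1 - 1, c2 - 1, s, P);
    else E += P.ml_close + P.ml_branch * (nchild + 1) + P.ml_unpaired * unp;
  }
  return List::create(_["energy"] = E, _["bad_i"] = 0, _["bad_j"] = 0);
}

// --- partition function ----------------------------------------------------

// Full equilibrium partition function Z = sum over all pseudoknot-free
// structures (min hairpin 3) of exp(-E(S)/RT), by O(n^3) inside recursion
// with interior loops capped at `maxloop` unpaired residues. Returns log Z.
// `qscale` is a per-nucleotide rescaling factor (weights divided by
// qscale^length) guarding against overflow on long inputs; the returned
// log Z is scale-independent.
// [[Rcpp::export]]
double c_partition(IntegerVector codes, List par, double RT, double qscale) {
  EPar P = make_par(par);
  int n = codes.size();
  std::vector<int> s(codes.begin(), codes.end());
  double lsc = std::log(qscale);
  std::vector<std::vector<double> > qb(n, std::vector<double>(n, 0.0)),
      qm(n, std::vector<double>(n, 0.0)), qm1(n, std::vector<double>(n, 0.0));
  for (int j = 0; j < n; j++) {
    for (int i = j - 4; i >= 0; i--) {
      if (pair_type(s[i], s[j])) {
        double q = std::exp(-hairpin_E(i, j, P) / RT - (j - i + 1) * lsc);
        for (int k = i + 1; k <= std::min(j - 5, i + P.maxloop + 1); k++) {
          int lmin = std::max(k + 4, j - 1 - P.maxloop + (k - i - 1));
          for (int l = std::max(lmin, k + 4); l < j; l++) {
            if (qb[k][l] == 0.0) continue;
            q += std::exp(-two_loop_E(i, j, k, l, s, P) / RT -
                          ((k - i) + (j - l)) * lsc) * qb[k][l];
          }
        }
        double qml = 0.0;
        for (int u = i + 2; u <= j - 5; u++)
          if (qm[i + 1][u - 1] != 0.0 && qm1[u][j - 1] != 0.0)
            qml += qm[i + 1][u - 1] * qm1[u][j - 1];
        q += std::exp(-(P.ml_close + P.ml_branch) / RT - 2 * lsc) * qml;
        qb[i][j] = q;
      }
      // qm1: exactly one branch starting at i, trailing bases unpaired
      double v1 = 0.0;
      for (int l = i + 4; l <= j; l++)
        if (qb[i][l] != 0.0)
          v1 += qb[i][l] * std::exp(-(P.ml_branch + P.ml_unpaired * (j - l)) /
                                    RT - (j - l) * lsc);
      qm1[i][j] = v1;
      // qm: >= 1 branch; decomposition by the start of the last branch
      double vm = 0.0;
      for (int k = i; k <= j - 4; k++) {
        if (qm1[k][j] == 0.0) continue;
        double before = std::exp(-(P.ml_unpaired * (k - i)) / RT - (k - i) * lsc);
        if (k > i) before += qm[i][k - 1];
        vm += before * qm1[k][j];
      }
      qm[i][j] = vm;
    }
  }
  // exterior loop
  std::vector<double> q(n, 0.0);
  for (int j = 0; j < n; j++) {
    double v = (j == 0 ? 1.0 : q[j - 1]) * std::exp(-lsc);
    for (int k = 0; k <= j - 4; k++)
      if (qb[k][j] != 0.0) v += (k == 0 ? 1.0 : q[k - 1]) * qb[k][j];
    q[j] = v;
  }
  return std::log(q[n - 1]) + n * lsc;
}

// --- MFE folding -----------------------------------------------------------

struct MfeArr {
  std::vector<std::vector<double> > v, wm, wm1;
  std::vector<double> w;
};

// deterministic traceback; scan order (hairpin, then interior loops by
// ascending k then l, then multiloop splits by ascending u) fixes ties.
static void trace_v(int i, int j, const std::vector<int>& s, const EPar& P,
                    const MfeArr& A, std::vector<int>& pt);

static void trace_wm1(int i, int j, const std::vector<int>& s, const EPar& P,
                      const MfeArr& A, std::vector<int>& pt) {
  for (int l = i + 4; l <= j; l++) {
    if (A.v[i][l] >= INF_E / 2) continue;
    double e = A.v[i][l] + P.ml_branch + P.ml_unpaired * (j - l);
    if (std::abs(e - A.wm1[i][j]) < 1e-7) { trace_v(i, l, s, P, A, pt); return; }
  }
  Rcpp::stop("traceback failure (wm1)");
}

static void trace_wm(int i, int j, const std::vector<int>& s, const EPar& P,
                     const MfeArr& A, std::vector<int>& pt) {
  for (int k = i; k <= j - 4; k++) {
    if (A.wm1[k][j] >= INF_E / 2) continue;
    double solo = P.ml_unpaired * (k - i) + A.wm1[k][j];
    if (std::abs(solo - A.wm[i][j]) < 1e-7) { trace_wm1(k, j, s, P, A, pt); return; }
    if (k > i && A.wm[i][k - 1] < INF_E / 2) {
      double split = A.wm[i][k - 1] + A.wm1[k][j];
      if (std::abs(split - A.wm[i][j]) < 1e-7) {
        trace_wm(i, k - 1, s, P, A, pt);
        trace_wm1(k, j, s, P, A, pt);
        return;
      }
    }
  }
  Rcpp::stop("traceback failure (wm)");
}

static void trace_v(int i, int j, const std::vector<int>& s, const EPar& P,
                    const MfeArr& A, std::vector<int>& pt) {
  pt[i + 1] = j + 1; pt[j + 1] = i + 1;
  double target = A.v[i][j];
  if (std::abs(hairpin_E(i, j, P) - target) < 1e-7) return;
  for (int k = i + 1; k <= std::min(j - 5, i + P.maxloop + 1); k++)
    for (int l = std::max(k + 4, j - 1 - P.maxloop + (k - i - 1)); l < j; l++) {
      if (A.v[k][l] >= INF_E / 2) continue;
      double e = two_loop_E(i, j, k, l, s, P) + A.v[k][l];
      if (std::abs(e - target) < 1e-7) { trace_v(k, l, s, P, A, pt); return; }
    }
  for (int u = i + 2; u <= j - 5; u++) {
    if (A.wm[i + 1][u - 1] >= INF_E / 2 || A.wm1[u][j - 1] >= INF_E / 2)
      continue;
    double e = P.ml_close + P.ml_branch + A.wm[i + 1][u - 1] + A.wm1[u][j - 1];
    if (std::abs(e - target) < 1e-7) {
      trace_wm(i + 1, u - 1, s, P, A, pt);
      trace_wm1(u, j - 1, s, P, A, pt);
      return;
    }
  }
  Rcpp::stop("traceback failure (v)");
}

// [[Rcpp::export]]
List c_mfe(IntegerVector codes, List par) {
  EPar P = make_par(par);
  int n = codes.size();
  std::vector<int> s(codes.begin(), codes.end());
  MfeArr A;
  A.v.assign(n, std::vector<double>(n, INF_E));
  A.wm.assign(n, std::vector<double>(n, INF_E));
  A.wm1.assign(n, std::vector<double>(n, INF_E));
  for (int j = 0; j < n; j++) {
    for (int i = j - 4; i >= 0; i--) {
      if (pair_type(s[i], s[j])) {
        double best = hairpin_E(i, j, P);
        for (int k = i + 1; k <= std::min(j - 5, i + P.maxloop + 1); k++)
          for (int l = std::max(k + 4, j - 1 - P.maxloop + (k - i - 1)); l < j;
               l++) {
            if (A.v[k][l] >= INF_E / 2) continue;
            best = std::min(best, two_loop_E(i, j, k, l, s, P) + A.v[k][l]);
          }
        for (int u = i + 2; u <= j - 5; u++)
          if (A.wm[i + 1][u - 1] < INF_E / 2 && A.wm1[u][j - 1] < INF_E / 2)
            best = std::min(best, P.ml_close + P.ml_branch +
                                      A.wm[i + 1][u - 1] + A.wm1[u][j - 1]);
        A.v[i][j] = best;
      }
      double v1 = INF_E;
      for (int l = i + 4; l <= j; l++)
        if (A.v[i][l] < INF_E / 2)
          v1 = std::min(v1, A.v[i][l] + P.ml_branch + P.ml_unpaired * (j - l));
      A.wm1[i][j] = v1;
      double vm = INF_E;
      for (int k = i; k <= j - 4; k++) {
        if (A.wm1[k][j] >= INF_E / 2) continue;
        vm = std::min(vm, P.ml_unpaired * (k - i) + A.wm1[k][j]);
        if (k > i && A.wm[i][k - 1] < INF_E / 2)
          vm = std::min(vm, A.wm[i][k - 1] + A.wm1[k][j]);
      }
      A.wm[i][j] = vm;
    }
  }
  A.w.assign(n, 0.0);
  for (int j = 0; j < n; j++) {
    double v = (j == 0 ? 0.0 : A.w[j - 1]);
    for (int k = 0; k <= j - 4; k++)
      if (A.v[k][j] < INF_E / 2)
        v = std::min(v, (k == 0 ? 0.0 : A.w[k - 1]) + A.v[k][j]);
    A.w[j] = v;
  }
  // exterior traceback: j unpaired when that preserves the optimum,
  // otherwise the 5'-most pair (k, j) achieving it.
  std::vector<int> pt(n + 1, 0);
  int j = n - 1;
  while (j >= 4) {
    if (std::abs(A.w[j] - A.w[j - 1]) < 1e-9) { j--; continue; }
    bool found = false;
    for (int k = 0; k <= j - 4; k++) {
      if (A.v[k][j] >= INF_E / 2) continue;
      double e = (k == 0 ? 0.0 : A.w[k - 1]) + A.v[k][j];
      if (std::abs(e - A.w[j]) < 1e-7) {
        trace_v(k, j, s, P, A, pt);
        j = k - 1; found = true; break;
      }
    }
    if (!found) Rcpp::stop("traceback failure (exterior)");
  }
  return List::create(_["energy"] = A.w[n - 1],
                      _["ptab"] = IntegerVector(pt.begin() + 1, pt.end()));
}
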