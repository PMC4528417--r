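// Three-taxon attachment scoring kernel.
//
// A query segment attached to a branch of the reference tree is scored as a
// three-taxon star: the internal node state x is summed over with prior
// bf[x], receiving messages from (a) the rest of the tree on the parent
// side of the branch (outside partial Ou), (b) the subtree below the branch
// (inside partial Du) and (c) the query itself. Branch lengths t_p, t_c,
// t_q are optimised by cyclic univariate Brent search. Columns are
// compressed to unique (partial-pattern class, query base) patterns.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static void pmat(const double* U, const double* Uinv, const double* lam,
                 double t, double* P) {
  double e[4];
  for (int l = 0; l < 4; ++l) e[l] = std::exp(lam[l] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int l = 0; l < 4; ++l) s += U[i + 4 * l] * e[l] * Uinv[l + 4 * j];
      P[i + 4 * j] = s > 0.0 ? s : 0.0;
    }
}

struct SegData {
  // aggregated patterns
  std::vector<int> klass;   // index into the used-class arrays below
  std::vector<int> qb;      // query base 0..3, 4 = missing
  std::vector<double> cnt;  // pattern multiplicities
  std::vector<double> Ouu, Duu;  // 4 x n_used partials (used classes only)
  int K;                    // number of used classes
  const double* U; const double* Uinv; const double* lam; const double* bf;

  double loglik(double tp, double tc, double tq) const {
    if (klass.empty()) return 0.0;
    double Pp[16], Pc[16], Pq[16];
    pmat(U, Uinv, lam, tp, Pp);
    pmat(U, Uinv, lam, tc, Pc);
    pmat(U, Uinv, lam, tq, Pq);
    std::vector<double> AB(4 * K);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < 4; ++i) {
        double sa = 0.0, sb = 0.0;
        for (int j = 0; j < 4; ++j) {
          sa += Pp[i + 4 * j] * Ouu[j + 4 * k];
          sb += Pc[i + 4 * j] * Duu[j + 4 * k];
        }
        AB[i + 4 * k] = bf[i] * sa * sb;
      }
    double ll = 0.0;
    const size_t M = klass.size();
    for (size_t m = 0; m < M; ++m) {
      const int k = klass[m], b = qb[m];
      double s = 0.0;
      if (b < 4) {
        for (int i = 0; i < 4; ++i)
          s += AB[i + 4 * k] * Pq[i + 4 * b];
      } else {
        for (int i = 0; i < 4; ++i)
          s += AB[i + 4 * k];
      }
      if (s < 1e-300) s = 1e-300;
      ll += cnt[m] * std::log(s);
    }
    return ll;
  }
};

// Brent minimisation of f on [a, b]; returns argmin, sets *fmin.
template <typename F>
static double brent(F f, double a, double b, double tol, double* fmin) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 80; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol + 1e-10 * std::fabs(x);
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e; e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) { e = (x >= xm) ? a - x : b - x; d = gold * e; }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u; fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fmin = fx;
  return x;
}

// optimise the three branch lengths of one segment by cyclic Brent
static double fit_segment(const SegData& seg, double* t, double lo, double hi,
                          double tol_ll, int max_cycles) {
  if (seg.klass.empty()) return 0.0;
  double ll = seg.loglik(t[0], t[1], t[2]);
  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    for (int which = 0; which < 3; ++which) {
      double fmin;
      auto f = [&](double x) {
        double tt[3] = { t[0], t[1], t[2] };
        tt[which] = x;
        return -seg.loglik(tt[0], tt[1], tt[2]);
      };
      double best = brent(f, lo, hi, 1e-5, &fmin);
      // keep an explicit zero-length candidate: boundary optima are common
      double tt[3] = { t[0], t[1], t[2] }; tt[which] = lo;
      double fz = -seg.loglik(tt[0], tt[1], tt[2]);
      if (fz <= fmin) { best = lo; fmin = fz; }
      t[which] = best;
    }
    double ll2 = seg.loglik(t[0], t[1], t[2]);
    if (ll2 - ll < tol_ll) { ll = ll2; break; }
    ll = ll2;
  }
  return ll;
}

static SegData make_seg(const NumericMatrix& Ou, const NumericMatrix& Du,
                        const IntegerVector& klass, const IntegerVector& qb,
                        const NumericMatrix& eigU, const NumericMatrix& eigUinv,
                        const NumericVector& lam, const NumericVector& bf,
                        int from, int to /* [from, to) site range */) {
  SegData s;
  s.U = REAL(eigU); s.Uinv = REAL(eigUinv);
  s.lam = REAL(lam); s.bf = REAL(bf);
  const int Kall = Ou.ncol();
  const double* ou = REAL(Ou); const double* du = REAL(Du);
  // aggregate (class, qb) patterns over the site range
  std::vector<double> acc((size_t)Kall * 5, 0.0);
  for (int i = from; i < to; ++i) {
    int key = klass[i] * 5 + qb[i];
    acc[key] += 1.0;
  }
  std::vector<int> used(Kall, -1);
  for (size_t key = 0; key < acc.size(); ++key)
    if (acc[key] > 0) {
      int kall = (int)(key / 5);
      if (used[kall] < 0) {
        used[kall] = (int)(s.Ouu.size() / 4);
        for (int i = 0; i < 4; ++i) {
          s.Ouu.push_back(ou[i + 4 * kall]);
          s.Duu.push_back(du[i + 4 * kall]);
        }
      }
      s.klass.push_back(used[kall]);
      s.qb.push_back((int)(key % 5));
      s.cnt.push_back(acc[key]);
    }
  s.K = (int)(s.Ouu.size() / 4);
  return s;
}

// [[Rcpp::export]]
List cpp_segment_fit(NumericMatrix eigU, NumericMatrix eigUinv,
                     NumericVector lam, NumericVector bf,
                     NumericMatrix Ou, NumericMatrix Du,
                     IntegerVector klass, IntegerVector qb,
                     NumericVector init, double lo, double hi,
                     double tol_ll, int max_cycles) {
  SegData s = make_seg(Ou, Du, klass, qb, eigU, eigUinv, lam, bf,
                       0, klass.size());
  double t[3] = { init[0], init[1], init[2] };
  double ll = fit_segment(s, t, lo, hi, tol_ll, max_cycles);
  return List::create(_["logL"] = ll,
                      _["lengths"] = NumericVector::create(t[0], t[1], t[2]));
}

// [[Rcpp::export]]
double cpp_segment_loglik(NumericMatrix eigU, NumericMatrix eigUinv,
                          NumericVector lam, NumericVector bf,
                          NumericMatrix Ou, NumericMatrix Du,
                          IntegerVector klass, IntegerVector qb,
                          NumericVector t) {
  SegData s = make_seg(Ou, Du, klass, qb, eigU, eigUinv, lam, bf,
                       0, klass.size());
  return s.loglik(t[0], t[1], t[2]);
}

// Scan one (V edge, J edge) pair over a vector of breakpoints.
// V sites and J sites are each sorted by query position; for breakpoint b
// the V segment is the prefix of V sites with qpos < b and the J segment
// the suffix of J sites with qpos >= b. Fits are warm-started along the
// breakpoint grid. Returns per-breakpoint logL (V+J, without the
// stationary background term added in R) and the six branch lengths.
// [[Rcpp::export]]
List cpp_pair_scan(NumericMatrix eigUv, NumericMatrix eigUinvv,
                   NumericVector lamv, NumericVector bfv,
                   NumericMatrix OuV, NumericMatrix DuV,
                   IntegerVector vklass, IntegerVector vqb,
                   IntegerVector vqpos,
                   NumericMatrix eigUj, NumericMatrix eigUinvj,
                   NumericVector lamj, NumericVector bfj,
                   NumericMatrix OuJ, NumericMatrix DuJ,
                   IntegerVector jklass, IntegerVector jqb,
                   IntegerVector jqpos,
                   IntegerVector bps, NumericVector initV,
                   NumericVector initJ, double lo, double hi,
                   double tol_ll, int max_cycles) {
  const int nb = bps.size();
  NumericVector llv(nb), llj(nb);
  NumericMatrix lens(nb, 6);
  double tv[3] = { initV[0], initV[1], initV[2] };
  double tj[3] = { initJ[0], initJ[1], initJ[2] };
  int prev_vcut = -1, prev_jcut = -1;
  double ll_v = 0.0, ll_j = 0.0;
  for (int r = 0; r < nb; ++r) {
    const int b = bps[r];
    int vcut = (int)(std::upper_bound(vqpos.begin(), vqpos.end(), b - 1) -
                     vqpos.begin());
    int jcut = (int)(std::lower_bound(jqpos.begin(), jqpos.end(), b) -
                     jqpos.begin());
    if (vcut != prev_vcut) {
      SegData sv = make_seg(OuV, DuV, vklass, vqb, eigUv, eigUinvv,
                            lamv, bfv, 0, vcut);
      ll_v = fit_segment(sv, tv, lo, hi, tol_ll, max_cycles);
      prev_vcut = vcut;
    }
    if (jcut != prev_jcut) {
      SegData sj = make_seg(OuJ, DuJ, jklass, jqb, eigUj, eigUinvj,
                            lamj, bfj, jcut, jklass.size());
      ll_j = fit_segment(sj, tj, lo, hi, tol_ll, max_cycles);
      prev_jcut = jcut;
    }
    llv[r] = ll_v; llj[r] = ll_j;
    for (int k = 0; k < 3; ++k) { lens(r, k) = tv[k]; lens(r, 3 + k) = tj[k]; }
  }
  return List::create(_["logL_v"] = llv, _["logL_j"] = llj,
                      _["lengths"] = lens);
}
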