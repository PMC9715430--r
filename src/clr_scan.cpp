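// Composite likelihood ratio scan for a fixed hard sweep.
//
// The sweep model distorts the genome-wide background SFS through the
// per-lineage escape probability p_e = 1 - exp(-alpha * d).  Conditional on
// the pre-sweep derived frequency f = j/n_ref (drawn from the background
// spectrum) and on the hitchhiking haplotype's allele, the derived count in
// a sample of n lineages is
//   n - Binomial(n, p_e (1 - f))  with probability f   (hitchhiker derived)
//   Binomial(n, p_e f)            with probability 1-f (hitchhiker ancestral)
// which follows because a lineage is ancestral iff it escapes and draws the
// ancestral allele (and conversely).  Class probabilities are restricted to
// polymorphic outcomes 1..n-1 and renormalised; the null model is the same
// construction at p_e = 1 (exact nesting, so CLR >= 0).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// full binomial pmf vector 0..n by stable recurrence
void binom_pmf(int n, double p, std::vector<double> &out) {
  out.assign(n + 1, 0.0);
  if (p <= 0.0) { out[0] = 1.0; return; }
  if (p >= 1.0) { out[n] = 1.0; return; }
  if (p <= 0.5) {
    double v = n * std::log1p(-p);
    v = std::exp(v);
    double ratio = p / (1.0 - p);
    out[0] = v;
    for (int k = 0; k < n; ++k) {
      v *= ratio * (double) (n - k) / (double) (k + 1);
      out[k + 1] = v;
    }
  } else {
    double v = std::exp(n * std::log(p));
    double ratio = (1.0 - p) / p;
    out[n] = v;
    for (int k = n; k > 0; --k) {
      v *= ratio * (double) k / (double) (n - k + 1);
      out[k - 1] = v;
    }
  }
}

// unnormalised sweep-model class probabilities over counts 0..n
void sweep_class_probs(const std::vector<double> &bg, int n_ref, int n,
                       double pe, std::vector<double> &probs) {
  probs.assign(n + 1, 0.0);
  std::vector<double> b1, b2;
  for (int j = 1; j <= n_ref - 1; ++j) {
    double w = bg[j - 1];
    if (w <= 0.0) continue;
    double f = (double) j / n_ref;
    binom_pmf(n, pe * (1.0 - f), b1); // hitchhiker derived: count = n - X
    binom_pmf(n, pe * f, b2);         // hitchhiker ancestral: count = X
    for (int k = 0; k <= n; ++k)
      probs[k] += w * (f * b1[n - k] + (1.0 - f) * b2[k]);
  }
}

} // namespace

// [[Rcpp::export(name = ".sweep_sfs_cpp")]]
List sweep_sfs_cpp(NumericVector bg, int n_ref, int n, double pe,
                   bool folded) {
  std::vector<double> bgv(bg.begin(), bg.end());
  std::vector<double> probs;
  sweep_class_probs(bgv, n_ref, n, pe, probs);
  double retention = 0.0;
  for (int k = 1; k <= n - 1; ++k) retention += probs[k];
  int nclass = folded ? n / 2 : n - 1;
  NumericVector out(nclass);
  if (retention > 0.0) {
    if (folded) {
      for (int k = 1; k <= n / 2; ++k) {
        double v = probs[k];
        if (n - k != k && n - k <= n - 1) v += probs[n - k];
        out[k - 1] = v / retention;
      }
    } else {
      for (int k = 1; k <= n - 1; ++k) out[k - 1] = probs[k] / retention;
    }
  }
  return List::create(_["probs"] = out, _["retention"] = retention);
}

// Log-probability tables: for each distinct sample size n and each p_e bin,
// the conditional (polymorphic, optionally folded) class log-probabilities.
// p_e bins are log-spaced in w = alpha * d; the final column is p_e = 1
// exactly (the null model).
// [[Rcpp::export(name = ".clr_tables_cpp")]]
List clr_tables_cpp(NumericVector bg, int n_ref, IntegerVector n_values,
                    bool folded, int n_bins, double w_min, double w_max) {
  std::vector<double> bgv(bg.begin(), bg.end());
  int nn = n_values.size();
  List tabs(nn);
  NumericVector wgrid(n_bins + 1);
  double lmin = std::log(w_min), lmax = std::log(w_max);
  for (int b = 0; b < n_bins; ++b)
    wgrid[b] = std::exp(lmin + (lmax - lmin) * b / (double) (n_bins - 1));
  wgrid[n_bins] = R_PosInf; // p_e = 1 column
  std::vector<double> probs;
  for (int q = 0; q < nn; ++q) {
    int n = n_values[q];
    int nclass = folded ? n / 2 : n - 1;
    NumericMatrix tab(n_bins + 1, nclass);
    for (int b = 0; b <= n_bins; ++b) {
      double pe = b < n_bins ? -std::expm1(-wgrid[b]) : 1.0;
      sweep_class_probs(bgv, n_ref, n, pe, probs);
      double ret = 0.0;
      for (int k = 1; k <= n - 1; ++k) ret += probs[k];
      for (int c = 1; c <= nclass; ++c) {
        double v = folded ?
          (probs[c] + ((n - c != c) ? probs[n - c] : 0.0)) : probs[c];
        v = ret > 0.0 ? v / ret : 0.0;
        tab(b, c - 1) = v > 0.0 ? std::log(v) : -745.0;
      }
    }
    tabs[q] = tab;
  }
  return List::create(_["tables"] = tabs, _["n_values"] = n_values,
                      _["n_bins"] = n_bins, _["w_min"] = w_min,
                      _["w_max"] = w_max, _["folded"] = folded,
                      _["n_ref"] = n_ref);
}

namespace {

// window scratch: per site a pointer to its table column (contiguous in the
// p_e-bin index) and the precomputed scaled log distance
struct ScanWindow {
  std::vector<const double *> cp;
  std::vector<double> u; // (log d - log w_min) * linv; -inf flag for d = 0
  double linv;
  int n_bins;
};

// log-likelihood of the current window under intensity alpha
double loglik_alpha(const ScanWindow &wnd, int nw, double alpha) {
  double ll = 0.0;
  double a = std::log(alpha) * wnd.linv;
  double top = (double) (wnd.n_bins - 1);
  for (int i = 0; i < nw; ++i) {
    double bf = wnd.u[i] + a;
    const double *col = wnd.cp[i];
    if (bf <= 0.0) {
      ll += col[0];
    } else if (bf >= top) {
      ll += col[wnd.n_bins]; // p_e = 1 column
    } else {
      int b = (int) bf;
      double fr = bf - b;
      ll += col[b] + fr * (col[b + 1] - col[b]);
    }
  }
  return ll;
}

} // namespace

// [[Rcpp::export(name = ".clr_scan_cpp")]]
List clr_scan_cpp(NumericVector site_pos, IntegerVector site_k,
                  IntegerVector site_nidx, List tables, NumericVector grid,
                  NumericVector alpha_grid, double radius, int n_bins,
                  double w_min, double w_max, int refine_iter,
                  int pre_scan) {
  int S = site_pos.size(), G = grid.size(), A = alpha_grid.size();
  std::vector<double> pos(site_pos.begin(), site_pos.end());
  std::vector<int> kidx(S), nidx(S);
  for (int i = 0; i < S; ++i) {
    kidx[i] = site_k[i] - 1;
    nidx[i] = site_nidx[i] - 1;
  }
  std::vector<NumericMatrix> tabs;
  for (int q = 0; q < tables.size(); ++q)
    tabs.push_back(as<NumericMatrix>(tables[q]));

  double lmin = std::log(w_min);
  double linv = (double) (n_bins - 1) / (std::log(w_max) - lmin);

  // per-site table-column pointer, null log-likelihood and prefix sums
  std::vector<const double *> sitecol(S);
  std::vector<double> l0pre(S + 1, 0.0);
  for (int i = 0; i < S; ++i) {
    const NumericMatrix &tab = tabs[nidx[i]];
    sitecol[i] = &tab(0, kidx[i]);
    l0pre[i + 1] = l0pre[i] + sitecol[i][n_bins];
  }
  ScanWindow wnd;
  wnd.linv = linv;
  wnd.n_bins = n_bins;
  wnd.cp.resize(S);
  wnd.u.resize(S);

  NumericVector clr(G), ahat(G);
  int i0 = 0, i1 = 0;
  const double invphi = 0.6180339887498949;
  for (int gi = 0; gi < G; ++gi) {
    double g = grid[gi];
    while (i0 < S && pos[i0] < g - radius) ++i0;
    if (i1 < i0) i1 = i0;
    while (i1 < S && pos[i1] <= g + radius) ++i1;
    if (i1 - i0 == 0) {
      clr[gi] = 0.0;
      ahat[gi] = NA_REAL;
      continue;
    }
    double l0 = l0pre[i1] - l0pre[i0];
    int nw = i1 - i0;
    for (int i = 0; i < nw; ++i) {
      double d = std::fabs(pos[i0 + i] - g);
      wnd.u[i] = d > 0.0 ? (std::log(d) - lmin) * linv : -1e300;
      wnd.cp[i] = sitecol[i0 + i];
    }
    double best = R_NegInf, besta = alpha_grid[0];
    int bestj = 0, secondj = -1;
    std::vector<double> lls(A);
    for (int j = 0; j < A; ++j) {
      double ll = loglik_alpha(wnd, nw, alpha_grid[j]);
      lls[j] = ll;
      if (ll > best + 1e-12) { // ties broken toward smaller alpha
        best = ll;
        besta = alpha_grid[j];
        bestj = j;
      }
    }
    // second-best local maximum outside the best bracket (the interpolated
    // likelihood surface can hold near-tied local optima)
    double second = R_NegInf;
    for (int j = 0; j < A; ++j) {
      if (std::abs(j - bestj) <= 1) continue;
      bool locmax = (j == 0 || lls[j] >= lls[j - 1]) &&
                    (j == A - 1 || lls[j] >= lls[j + 1]);
      if (locmax && lls[j] > second) {
        second = lls[j];
        secondj = j;
      }
    }
    // refinement on log alpha between bracketing grid points, applied to
    // the best (and second-best) brackets: the interpolated surface is
    // piecewise linear, so a sub-bin pre-scan locates the active segment
    // and golden-section polishes within it
    if (refine_iter > 0 && A > 1) {
      int cand[2] = {bestj, secondj};
      double refx = std::log(besta), refv = best;
      for (int ci = 0; ci < 2; ++ci) {
        int j0 = cand[ci];
        if (j0 < 0) continue;
        double blo = std::log(alpha_grid[j0 > 0 ? j0 - 1 : 0]);
        double bhi = std::log(alpha_grid[j0 < A - 1 ? j0 + 1 : A - 1]);
        if (bhi <= blo) continue;
        int P = pre_scan < 2 ? 2 : pre_scan;
        int kbest = 0;
        double vbest = R_NegInf;
        for (int k = 0; k <= P; ++k) {
          double x = blo + (bhi - blo) * k / P;
          double v = loglik_alpha(wnd, nw, std::exp(x));
          if (v > vbest + 1e-12) {
            vbest = v;
            kbest = k;
          }
          if (v > refv + 1e-12 || (v > refv - 1e-12 && x < refx)) {
            refv = v;
            refx = x;
          }
        }
        double lo = blo + (bhi - blo) * (kbest > 0 ? kbest - 1 : 0) / P;
        double hi = blo + (bhi - blo) * (kbest < P ? kbest + 1 : P) / P;
        double c = hi - invphi * (hi - lo), dd = lo + invphi * (hi - lo);
        double fc = loglik_alpha(wnd, nw, std::exp(c));
        double fd = loglik_alpha(wnd, nw, std::exp(dd));
        for (int it = 0; it < refine_iter; ++it) {
          if (fc >= fd) { // prefer the lower-alpha side on ties
            hi = dd;
            dd = c;
            fd = fc;
            c = hi - invphi * (hi - lo);
            fc = loglik_alpha(wnd, nw, std::exp(c));
          } else {
            lo = c;
            c = dd;
            fc = fd;
            dd = lo + invphi * (hi - lo);
            fd = loglik_alpha(wnd, nw, std::exp(dd));
          }
        }
        double xm = fc >= fd ? c : dd, fm = fc >= fd ? fc : fd;
        if (fm > refv + 1e-12 || (fm > refv - 1e-12 && xm < refx)) {
          refv = fm;
          refx = xm;
        }
      }
      if (refv > best) {
        best = refv;
        besta = std::exp(refx);
      }
    }
    double v = 2.0 * (best - l0);
    clr[gi] = v > 0.0 ? v : 0.0;
    ahat[gi] = besta;
  }
  return List::create(_["clr"] = clr, _["alpha_hat"] = ahat);
}
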