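// Discrete Wright-Fisher Monte-Carlo oracles for the sweep-origin theory:
// establishment/fixation of tagged beneficial lineages under additive
// selection (h = 0.5), with recurrent one-way mutation, a pre-shift
// deleterious phase and a bottleneck at the environmental shift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double sel_weight(double p, double s) {
  if (s == 0.0 || p <= 0.0 || p >= 1.0) return p;
  return p * (1.0 + s * (1.0 + p) / 2.0) / (1.0 + s * p);
}

inline int rbinom_int(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return (int) R::rbinom((double) n, p);
}

// multinomial reallocation of B1 offspring among lineages with counts c
void realloc_lineages(std::vector<int> &c, int B0, int B1) {
  int remaining = B1, tot = B0;
  for (size_t i = 0; i < c.size(); ++i) {
    if (tot <= 0) { c[i] = 0; continue; }
    int x = rbinom_int(remaining, (double) c[i] / tot);
    tot -= c[i];
    remaining -= x;
    c[i] = x;
  }
}

inline int count_surviving(const std::vector<int> &c) {
  int k = 0;
  for (size_t i = 0; i < c.size(); ++i) if (c[i] > 0) ++k;
  return k;
}

void compact(std::vector<int> &c) {
  size_t w = 0;
  for (size_t i = 0; i < c.size(); ++i) if (c[i] > 0) c[w++] = c[i];
  c.resize(w);
}

} // namespace

// Fixation (or threshold-hitting) probability of a single new copy.
// [[Rcpp::export(name = ".wf_fix_single")]]
List wf_fix_single(int twoN, double s, double thresh, int n_rep) {
  int hits = 0;
  for (int r = 0; r < n_rep; ++r) {
    int x = 1;
    for (;;) {
      double p = (double) x / twoN;
      if (thresh < 1.0 && p >= thresh) { ++hits; break; }
      if (x == 0) break;
      if (x == twoN) { if (thresh >= 1.0) ++hits; break; }
      x = rbinom_int(twoN, sel_weight(p, s));
    }
  }
  double ph = (double) hits / n_rep;
  return List::create(_["p"] = ph,
                      _["se"] = std::sqrt(ph * (1 - ph) / n_rep),
                      _["n_rep"] = n_rep);
}

// De novo path: origin-tagged mutational input restricted to the first
// t_input generations; run to fixation or loss of all copies.
// [[Rcpp::export(name = ".wf_oracle_denovo")]]
List wf_oracle_denovo(int twoN, double s_b, double muL, int t_input,
                      int n_rep, int max_gen) {
  int fixed = 0, hard = 0;
  for (int r = 0; r < n_rep; ++r) {
    std::vector<int> lin;
    int B = 0;
    for (int t = 0; t < max_gen; ++t) {
      if (B == twoN) break;
      double p = (double) B / twoN;
      int B1 = rbinom_int(twoN, sel_weight(p, s_b));
      realloc_lineages(lin, B, B1);
      B = B1;
      if (t < t_input) {
        int nnew = (int) R::rpois((double) twoN * (1.0 - p) * muL);
        for (int m = 0; m < nnew && B < twoN; ++m) {
          lin.push_back(1);
          ++B;
        }
      }
      compact(lin);
      if (B == 0 && t >= t_input) break;
    }
    if (B == twoN) {
      ++fixed;
      if (count_surviving(lin) == 1) ++hard;
    }
  }
  double pf = (double) fixed / n_rep;
  double phard = fixed > 0 ? (double) hard / fixed : NA_REAL;
  return List::create(_["p_fix"] = pf,
                      _["se_fix"] = std::sqrt(pf * (1 - pf) / n_rep),
                      _["p_hard"] = phard,
                      _["se_hard"] = fixed > 0 ?
                        std::sqrt(phard * (1 - phard) / fixed) : NA_REAL,
                      _["n_fixed"] = fixed, _["n_rep"] = n_rep);
}

// Reduced standing-variation hardness computation: the allele frequency at
// the shift is drawn from the analytic mutation-selection-drift density
// Theta * x^(Theta-1) * exp(-alpha_d * x), each surviving copy after the
// bottleneck is tagged, and the beneficial class is run to fixation/loss
// exactly.  Used by the hardness calculator; the full explicit-phase oracle
// below remains its independent cross-check.
// [[Rcpp::export(name = ".wf_hard_sgv_reduced")]]
List wf_hard_sgv_reduced(int twoN_post, double s_b, double theta,
                         double alpha_d, double x_min, int n_rep,
                         int max_gen) {
  // discretised inverse-CDF sampler for the standing density on [x_min, 1]
  const int ngrid = 2048;
  std::vector<double> xg(ngrid), cw(ngrid);
  double lmin = std::log(x_min);
  double acc = 0.0;
  for (int i = 0; i < ngrid; ++i) {
    double u = lmin + (0.0 - lmin) * (i + 0.5) / ngrid;
    double x = std::exp(u);
    xg[i] = x;
    // density in log-x coordinates: x^Theta * exp(-alpha_d x)
    acc += std::exp(theta * u - alpha_d * x);
    cw[i] = acc;
  }
  int fixed = 0, hard = 0;
  for (int r = 0; r < n_rep; ++r) {
    double uu = unif_rand() * acc;
    int lo = 0, hi = ngrid - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cw[mid] < uu) lo = mid + 1; else hi = mid;
    }
    double x = xg[lo];
    int j = rbinom_int(twoN_post, x);
    if (j == 0) continue;
    std::vector<int> lin(j, 1);
    int B = j;
    for (int t = 0; t < max_gen && B > 0 && B < twoN_post; ++t) {
      double p = (double) B / twoN_post;
      int B1 = rbinom_int(twoN_post, sel_weight(p, s_b));
      realloc_lineages(lin, B, B1);
      B = B1;
      compact(lin);
    }
    if (B == twoN_post) {
      ++fixed;
      if (count_surviving(lin) == 1) ++hard;
    }
  }
  double ph = fixed > 0 ? (double) hard / fixed : NA_REAL;
  return List::create(_["p_hard"] = ph,
                      _["se_hard"] = fixed > 0 ?
                        std::sqrt(ph * (1 - ph) / fixed) : NA_REAL,
                      _["n_fixed"] = fixed, _["n_rep"] = n_rep);
}

// Standing-variation path: explicit deleterious mutation-selection-drift
// phase at the ancestral size, bottleneck at the shift, each surviving
// standing copy tagged, beneficial phase run to fixation/loss without
// further mutational input (component isolation; see vignette).
// [[Rcpp::export(name = ".wf_oracle_sgv")]]
List wf_oracle_sgv(int twoN_anc, int twoN_post, double s_d, double s_b,
                   double muL, int burn_gens, int n_rep, int max_gen) {
  int fixed = 0, hard = 0;
  long long sum_standing = 0;
  for (int r = 0; r < n_rep; ++r) {
    // phase 1: total count only (origins irrelevant for copy-tagging)
    int x = 0;
    for (int t = 0; t < burn_gens; ++t) {
      double p = (double) x / twoN_anc;
      x = rbinom_int(twoN_anc, sel_weight(p, -s_d));
      int nnew = (int) R::rpois((double) twoN_anc * (1.0 - p) * muL);
      x = std::min(twoN_anc, x + nnew);
    }
    // shift: bottleneck, tag each surviving copy
    int x_post = rbinom_int(twoN_post, (double) x / twoN_anc);
    sum_standing += x_post;
    if (x_post == 0) continue;
    std::vector<int> lin(x_post, 1);
    int B = x_post;
    for (int t = 0; t < max_gen && B > 0 && B < twoN_post; ++t) {
      double p = (double) B / twoN_post;
      int B1 = rbinom_int(twoN_post, sel_weight(p, s_b));
      realloc_lineages(lin, B, B1);
      B = B1;
      compact(lin);
    }
    if (B == twoN_post) {
      ++fixed;
      if (count_surviving(lin) == 1) ++hard;
    }
  }
  double pf = (double) fixed / n_rep;
  double phard = fixed > 0 ? (double) hard / fixed : NA_REAL;
  return List::create(_["p_fix"] = pf,
                      _["se_fix"] = std::sqrt(pf * (1 - pf) / n_rep),
                      _["p_hard"] = phard,
                      _["se_hard"] = fixed > 0 ?
                        std::sqrt(phard * (1 - phard) / fixed) : NA_REAL,
                      _["n_fixed"] = fixed, _["n_rep"] = n_rep,
                      _["mean_standing_post"] = (double) sum_standing / n_rep);
}
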