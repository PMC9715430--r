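// Trajectory-conditioned Wright-Fisher engine for 5-Mb region replicates.
//
// Pass 1 simulates the selected locus exactly (diploid WF, additive fitness
// with h = 0.5) through a multi-branch demography with splits and admixture
// pulses, retrying until the establishment condition is met.  Pass 2 advances
// every neutral site as a two-locus system (derived counts on the beneficial
// and wild backgrounds) conditioned on that trajectory.  All downstream
// statistics in the package are per-site functionals, which this factorised
// representation reproduces; see the methods vignette.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

// marginal parental frequency of the beneficial allele after selection
// (fitnesses 1, 1 + s/2, 1 + s)
inline double sel_weight(double p, double s) {
  if (s == 0.0 || p <= 0.0 || p >= 1.0) return p;
  return p * (1.0 + s * (1.0 + p) / 2.0) / (1.0 + s * p);
}

// Binomial sampler with a variance-matched normal fast path far from the
// absorbing boundaries (npq > 50); boundary-adjacent dynamics stay exact.
inline int rbinom_int(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  double npq = n * p * (1.0 - p);
  if (npq > 50.0) {
    double x = std::floor(n * p + std::sqrt(npq) * norm_rand() + 0.5);
    if (x < 0.0) x = 0.0;
    if (x > n) x = (double) n;
    return (int) x;
  }
  return (int) R::rbinom((double) n, p);
}

struct Demography {
  int nb;
  std::vector<int> parent, sg, eg, twoN;
  std::vector<int> pgen, psrc, pdst;
  std::vector<double> pfrac;
  int G;
};

struct Selection {
  bool active;
  int branch, intro_gen, cease_gen; // cease_gen < 0: never
  double s;
};

typedef std::vector<std::vector<int> > Traj;

inline bool alive(const Demography &d, int b, int t) {
  return t >= d.sg[b] && t <= d.eg[b];
}

double simulate_trajectory(const Demography &d, const Selection &sel,
                           Traj &traj, double trigger_freq, int *trigger_gen) {
  traj.assign(d.nb, std::vector<int>());
  for (int b = 0; b < d.nb; ++b) traj[b].assign(d.eg[b] - d.sg[b] + 1, 0);
  *trigger_gen = -1;
  if (!sel.active) return 0.0;
  double maxf = 0.0;
  traj[sel.branch][sel.intro_gen - d.sg[sel.branch]] = 1;
  if (trigger_freq > 0.0 && 1.0 / d.twoN[sel.branch] >= trigger_freq) {
    *trigger_gen = sel.intro_gen;
    return 1.0 / d.twoN[sel.branch];
  }
  for (int t = sel.intro_gen; t < d.G; ++t) {
    double s_now = (sel.cease_gen >= 0 && t >= sel.cease_gen) ? 0.0 : sel.s;
    bool any = false;
    for (int b = 0; b < d.nb; ++b) {
      if (!alive(d, b, t + 1)) continue;
      int from = (t + 1 == d.sg[b]) ? d.parent[b] : b;
      if (from < 0 || !alive(d, from, t)) continue;
      int src_b = -1;
      double frac = 0.0;
      for (size_t k = 0; k < d.pgen.size(); ++k)
        if (d.pgen[k] == t + 1 && d.pdst[k] == b && alive(d, d.psrc[k], t)) {
          src_b = d.psrc[k];
          frac = d.pfrac[k];
        }
      double p_own = (double) traj[from][t - d.sg[from]] / d.twoN[from];
      double p_mix = sel_weight(p_own, s_now);
      if (src_b >= 0) {
        double p_src = (double) traj[src_b][t - d.sg[src_b]] / d.twoN[src_b];
        p_mix = frac * sel_weight(p_src, s_now) + (1.0 - frac) * p_mix;
      }
      int x = rbinom_int(d.twoN[b], p_mix);
      traj[b][t + 1 - d.sg[b]] = x;
      if (x > 0) any = true;
      double f = (double) x / d.twoN[b];
      if (f > maxf) maxf = f;
      if (trigger_freq > 0.0 && b == sel.branch && f >= trigger_freq &&
          *trigger_gen < 0) *trigger_gen = t + 1;
    }
    if (trigger_freq > 0.0 && *trigger_gen >= 0) return maxf;
    if (!any) return maxf; // lost everywhere; cannot recur
  }
  return maxf;
}

// background frequencies of a site in a source branch, respecting frozen
// (monomorphic) storage whose background split may be stale
inline void site_bg_freqs(int yB, int yW, int B0, int twoN0, double ps,
                          double rho, double *qBe, double *qWe) {
  int tot = yB + yW;
  double qB, qW;
  if (tot <= 0) {
    qB = qW = 0.0;
  } else if (tot >= twoN0) {
    qB = qW = 1.0;
  } else {
    qB = B0 > 0 ? (double) yB / B0 : 0.0;
    qW = twoN0 - B0 > 0 ? (double) yW / (twoN0 - B0) : 0.0;
    double qbar = ps * qB + (1.0 - ps) * qW;
    if (B0 == 0) qB = qbar;
    if (twoN0 - B0 == 0) qW = qbar;
    *qBe = (1.0 - rho) * qB + rho * qbar;
    *qWe = (1.0 - rho) * qW + rho * qbar;
    return;
  }
  *qBe = qB;
  *qWe = qW;
}

} // namespace

// [[Rcpp::export(name = ".wf_region_sim")]]
List wf_region_sim(IntegerVector br_parent, IntegerVector br_start,
                   IntegerVector br_end, IntegerVector br_twoN,
                   IntegerVector pulse_gen, IntegerVector pulse_src,
                   IntegerVector pulse_dst, NumericVector pulse_frac,
                   bool sel_active, int sel_branch, int sel_intro,
                   int sel_cease, double sel_s, double sel_pos,
                   NumericVector site_pos, IntegerVector site_x0,
                   IntegerVector site_fix_branch, double rho_per_bp,
                   double region_bp, bool new_mutations, double mu_per_bp,
                   IntegerVector samp_branch, IntegerVector samp_gen,
                   IntegerVector samp_nhap, double condition_min_freq,
                   double stop_at_freq, int max_tries) {
  Demography d;
  d.nb = br_parent.size();
  d.parent = as<std::vector<int> >(br_parent);
  d.sg = as<std::vector<int> >(br_start);
  d.eg = as<std::vector<int> >(br_end);
  d.twoN = as<std::vector<int> >(br_twoN);
  d.pgen = as<std::vector<int> >(pulse_gen);
  d.psrc = as<std::vector<int> >(pulse_src);
  d.pdst = as<std::vector<int> >(pulse_dst);
  d.pfrac = as<std::vector<double> >(pulse_frac);
  d.G = 0;
  for (int b = 0; b < d.nb; ++b) if (d.eg[b] > d.G) d.G = d.eg[b];

  Selection sel;
  sel.active = sel_active;
  sel.branch = sel_branch;
  sel.intro_gen = sel_intro;
  sel.cease_gen = sel_cease;
  sel.s = sel_s;

  // ---- pass 1: selected-locus trajectory with conditioning -------------
  Traj traj;
  int tries = 0, trigger_gen = -1;
  if (sel.active) {
    for (;;) {
      ++tries;
      double maxf = simulate_trajectory(d, sel, traj, stop_at_freq,
                                        &trigger_gen);
      bool ok = (condition_min_freq <= 0.0 || maxf >= condition_min_freq);
      if (stop_at_freq > 0.0) ok = trigger_gen >= 0;
      if (ok) break;
      if (tries >= max_tries)
        stop("establishment condition not met in %d attempts", max_tries);
    }
  } else {
    simulate_trajectory(d, sel, traj, -1.0, &trigger_gen);
    tries = 1;
  }
  int G_eff = (stop_at_freq > 0.0 && trigger_gen >= 0) ? trigger_gen : d.G;

  #define BCOUNT(b, t) (sel.active && alive(d, b, t) ? \
                        traj[b][(t) - d.sg[b]] : 0)

  // ---- pass 2: neutral sites conditioned on the trajectory -------------
  int S0 = site_pos.size();
  std::vector<double> pos(site_pos.begin(), site_pos.end());
  std::vector<double> rho(S0);
  for (int i = 0; i < S0; ++i)
    rho[i] = std::min(0.5, rho_per_bp * std::fabs(pos[i] - sel_pos));

  std::vector<std::vector<int> > yB(d.nb), yW(d.nb);
  std::vector<std::vector<unsigned char> > seg(d.nb);
  for (int b = 0; b < d.nb; ++b) {
    yB[b].assign(S0, 0);
    yW[b].assign(S0, 0);
    seg[b].assign(S0, 0);
  }
  for (int i = 0; i < S0; ++i) {
    yW[0][i] = site_x0[i];
    seg[0][i] = (site_x0[i] > 0 && site_x0[i] < d.twoN[0]) ? 1 : 0;
  }

  int n_samp = samp_branch.size();
  std::vector<IntegerMatrix> samples(n_samp);
  std::vector<IntegerVector> hapB(n_samp);
  std::vector<bool> sampled(n_samp, false);
  std::vector<double> sampP(n_samp, 0.0);

  for (int t = d.sg[0]; t <= G_eff; ++t) {
    if (t > d.sg[0]) {
      // snapshot branches read by a *different* branch this generation
      std::map<int, std::vector<int> > snapB, snapW;
      for (int b = 0; b < d.nb; ++b) {
        if (!alive(d, b, t)) continue;
        if (t == d.sg[b] && d.parent[b] >= 0 &&
            snapB.find(d.parent[b]) == snapB.end()) {
          snapB[d.parent[b]] = yB[d.parent[b]];
          snapW[d.parent[b]] = yW[d.parent[b]];
        }
      }
      for (size_t k = 0; k < d.pgen.size(); ++k)
        if (d.pgen[k] == t && snapB.find(d.psrc[k]) == snapB.end()) {
          snapB[d.psrc[k]] = yB[d.psrc[k]];
          snapW[d.psrc[k]] = yW[d.psrc[k]];
        }

      for (int b = 0; b < d.nb; ++b) {
        if (!alive(d, b, t)) continue;
        int from = (t == d.sg[b]) ? d.parent[b] : b;
        if (from < 0 || !alive(d, from, t - 1)) continue;
        int src_b = -1;
        double frac = 0.0;
        for (size_t k = 0; k < d.pgen.size(); ++k)
          if (d.pgen[k] == t && d.pdst[k] == b && alive(d, d.psrc[k], t - 1)) {
            src_b = d.psrc[k];
            frac = d.pfrac[k];
          }
        double s_now = (!sel.active ||
                        (sel.cease_gen >= 0 && t - 1 >= sel.cease_gen))
                       ? 0.0 : sel.s;
        int B1 = BCOUNT(b, t), twoN1 = d.twoN[b], W1 = twoN1 - B1;
        int B0a = BCOUNT(from, t - 1), twoN0a = d.twoN[from];
        double psa = sel_weight((double) B0a / twoN0a, s_now);
        int B0s = 0, twoN0s = 1;
        double pss = 0.0;
        if (src_b >= 0) {
          B0s = BCOUNT(src_b, t - 1);
          twoN0s = d.twoN[src_b];
          pss = sel_weight((double) B0s / twoN0s, s_now);
        }
        double wBs = 0.0, wWs = 0.0;
        if (src_b >= 0) {
          double denB = frac * pss + (1.0 - frac) * psa;
          wBs = denB > 0.0 ? frac * pss / denB : 0.0;
          double denW = frac * (1.0 - pss) + (1.0 - frac) * (1.0 - psa);
          wWs = denW > 0.0 ? frac * (1.0 - pss) / denW : 0.0;
        }
        bool cross = (b != from) || (src_b >= 0);
        const std::vector<int> &rBa = (from != b && snapB.count(from)) ?
          snapB[from] : yB[from];
        const std::vector<int> &rWa = (from != b && snapW.count(from)) ?
          snapW[from] : yW[from];
        const std::vector<int> &rBs = (src_b >= 0 && snapB.count(src_b)) ?
          snapB[src_b] : yB[src_b >= 0 ? src_b : from];
        const std::vector<int> &rWs = (src_b >= 0 && snapW.count(src_b)) ?
          snapW[src_b] : yW[src_b >= 0 ? src_b : from];
        int S = (int) pos.size();
        for (int i = 0; i < S; ++i) {
          if (!cross && !seg[b][i]) continue;
          if (cross) {
            int tota = rBa[i] + rWa[i];
            int tots = src_b >= 0 ? rBs[i] + rWs[i] : tota;
            bool froza = (tota == 0 || tota == twoN0a);
            bool frozs = src_b >= 0 ? (tots == 0 || tots == twoN0s) : froza;
            if (froza && frozs && ((tota > 0) == (tots > 0))) {
              int fx = tota > 0 ? 1 : 0;
              yB[b][i] = fx ? B1 : 0;
              yW[b][i] = fx ? W1 : 0;
              seg[b][i] = 0;
              continue;
            }
          }
          double qBe, qWe;
          site_bg_freqs(rBa[i], rWa[i], B0a, twoN0a, psa, rho[i], &qBe, &qWe);
          if (src_b >= 0) {
            double qBs, qWs;
            site_bg_freqs(rBs[i], rWs[i], B0s, twoN0s, pss, rho[i],
                          &qBs, &qWs);
            qBe = wBs * qBs + (1.0 - wBs) * qBe;
            qWe = wWs * qWs + (1.0 - wWs) * qWe;
          }
          int nB1 = rbinom_int(B1, qBe);
          int nW1 = rbinom_int(W1, qWe);
          yB[b][i] = nB1;
          yW[b][i] = nW1;
          int tot = nB1 + nW1;
          seg[b][i] = (tot > 0 && tot < twoN1) ? 1 : 0;
        }
        if (new_mutations) {
          int nnew = (int) R::rpois((double) twoN1 * mu_per_bp * region_bp);
          for (int m = 0; m < nnew; ++m) {
            double newpos = unif_rand() * region_bp;
            pos.push_back(newpos);
            rho.push_back(std::min(0.5,
                          rho_per_bp * std::fabs(newpos - sel_pos)));
            for (int bb = 0; bb < d.nb; ++bb) {
              yB[bb].push_back(0);
              yW[bb].push_back(0);
              seg[bb].push_back(0);
            }
            double pb = (double) B1 / twoN1;
            if (B1 > 0 && unif_rand() < pb) yB[b].back() = 1;
            else yW[b].back() = 1;
            seg[b].back() = 1;
          }
        }
      }
    }
    // branch-specific fixation overrides (ancestry markers) at founding
    for (int i = 0; i < (int) site_fix_branch.size(); ++i) {
      int fb = site_fix_branch[i];
      if (fb >= 0 && alive(d, fb, t) && t == d.sg[fb]) {
        int B = BCOUNT(fb, t);
        yB[fb][i] = B;
        yW[fb][i] = d.twoN[fb] - B;
        seg[fb][i] = 0;
      }
    }
    // scheduled samples (gen < 0 means: at the trigger generation)
    for (int q = 0; q < n_samp; ++q) {
      int tg = samp_gen[q] < 0 ? G_eff : samp_gen[q];
      if (tg != t || sampled[q]) continue;
      int b = samp_branch[q];
      if (!alive(d, b, t))
        stop("sample %d scheduled outside branch lifespan", q + 1);
      int n = samp_nhap[q];
      int B = BCOUNT(b, t), twoN = d.twoN[b];
      double p = (double) B / twoN;
      sampP[q] = p;
      int S = (int) pos.size();
      IntegerMatrix M(n, S);
      IntegerVector hb(n);
      for (int h = 0; h < n; ++h) hb[h] = (unif_rand() < p) ? 1 : 0;
      for (int i = 0; i < S; ++i) {
        int tot = yB[b][i] + yW[b][i];
        if (tot == 0) continue;
        if (tot == twoN) {
          for (int h = 0; h < n; ++h) M(h, i) = 1;
          continue;
        }
        double qB = B > 0 ? (double) yB[b][i] / B : 0.0;
        double qW = twoN - B > 0 ? (double) yW[b][i] / (twoN - B) : 0.0;
        for (int h = 0; h < n; ++h)
          M(h, i) = (unif_rand() < (hb[h] ? qB : qW)) ? 1 : 0;
      }
      samples[q] = M;
      hapB[q] = hb;
      sampled[q] = true;
    }
  }
  #undef BCOUNT

  List out_samp(n_samp), out_hapB(n_samp), out_traj(d.nb);
  for (int q = 0; q < n_samp; ++q) {
    if (!sampled[q]) stop("sample %d was never drawn (check times)", q + 1);
    out_samp[q] = samples[q];
    out_hapB[q] = hapB[q];
  }
  for (int b = 0; b < d.nb; ++b) out_traj[b] = wrap(traj[b]);
  return List::create(_["samples"] = out_samp, _["hap_benef"] = out_hapB,
                      _["trajectories"] = out_traj,
                      _["positions"] = wrap(pos), _["attempts"] = tries,
                      _["trigger_gen"] = trigger_gen, _["G_eff"] = G_eff,
                      _["sample_benef_freq"] = wrap(sampP));
}
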