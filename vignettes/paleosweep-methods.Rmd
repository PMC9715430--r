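---
title: "Detecting hard sweeps in ancient pseudohaploid data: models and methods"
author: "paleosweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hard sweeps in ancient pseudohaploid data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosweep)
```

# The problem

A classic ("hard") selective sweep drives a single beneficial haplotype to
fixation, stripping linked variation and skewing the site frequency
spectrum (SFS) toward rare and high-frequency derived alleles.  In
recently admixed populations -- modern Europeans being the canonical case,
with roughly equal ancestry from Western Hunter-Gatherers (WHG), Anatolian
early farmers and Steppe pastoralists -- admixture re-introduces
orthologous haplotypes and can dilute a completed sweep below detection
limits.  `paleosweep` implements a composite-likelihood sweep-detection
pipeline suited to pseudohaploid ancient-DNA genotype data, a forward
simulation framework for quantifying how admixture erodes sweep signals,
and closed-form calculators for whether such sweeps arise from de novo
mutations or standing genetic variation (SGV).

# The composite likelihood ratio

## Background spectrum and effective sample size

Pseudohaploid data provide one sampled allele per individual per site,
with heavy site-specific missingness.  Per population we reduce calls to
per-site records $(x, n)$ (derived count among non-missing calls) and
build the genome-wide background SFS: every site with $n \ge n_{ref}$
contributes its exact hypergeometric projection to a common size
$n_{ref}$ (default: the 5th percentile of per-site $n$, so at least 95%
of sites can be projected down; smaller sites are excluded from the
background but still scanned at their own $n$).  The background absorbs
demography, ascertainment and missingness, which is what makes the scan
robust to non-equilibrium history.  The effective sample size
$n_{eff} = k\,n\,(1 - M)$ (ploidy $k$, samples $n$, mean missingness $M$)
gates which populations have power; populations with $n_{eff} < 10$ are
excluded from sweep determination.

## Sweep model

A lineage sampled at distance $d$ from a swept site escapes the sweep
with probability $p_e = 1 - e^{-\alpha d}$, where $\alpha$ is the
composite sweep intensity (per bp).  Conditional on a pre-sweep derived
frequency $f = j/n_{ref}$ drawn from the background spectrum, each of $n$
lineages escapes independently and then carries the derived allele with
probability $f$, while all non-escapees inherit the hitchhiking
haplotype's single allele draw.  Collecting terms, the derived count is
$n - \mathrm{Bin}(n, p_e(1-f))$ with probability $f$ and
$\mathrm{Bin}(n, p_e f)$ with probability $1 - f$; the distribution is
restricted to polymorphic classes and renormalised (the data are an
ascertained variant-only panel, so the likelihood conditions on
polymorphism).  The null model is defined as the same construction at
$p_e \equiv 1$, not the raw background product: this guarantees exact
nesting and hence $CLR = 2(\max_\alpha L(\alpha) - L_0) \ge 0$ despite
the binomial-resampling approximation.  For folded data, classes $j$ and
$n - j$ are merged before likelihood evaluation and the projected
background is symmetrised.

## Numerics

Class log-probabilities are tabulated per sample size on a log-spaced
grid of $w = \alpha d$ (96 bins spanning $10^{-8}$ to 30, plus an exact
$p_e = 1$ column) and linearly interpolated, making the per-site
likelihood a table lookup.  $\alpha$ is maximised over a 40-point
log-spaced grid ($10^{-8}$ to $10^{-2}$ per bp) followed by refinement in
the bracketing interval; because the interpolated surface is piecewise
linear in $\log\alpha$, refinement first pre-scans the bracket at
sub-bin resolution and then applies golden-section polish, with ties
broken toward smaller $\alpha$.  Sites with $n$ above $n_{ref}$ are
hypergeometrically downsampled once (seeded) so tables never exceed
$n_{ref}$.  Scan positions follow a regular grid (1 kb for genome scans;
the simulation studies use 5 kb over 5-Mb regions, far below the
megabase-scale sweep footprint, with a 2-Mb site-inclusion radius).

## Polarisation

Reference-polarised data without ancestral calls are treated as folded by
default.  In simulation studies the ancestral state is known, and the
planted-sweep recovery experiment uses unfolded spectra: folding merges
the high-frequency-derived classes that carry much of the hard-sweep
signature, and there is no reason to discard that information when the
polarisation is exact.

# Gene scores, regions and presence

Scan tracks are reduced to gene evidence by taking the maximum of
$\ln(1 + CLR)$ over grid positions within each gene extended by 50 kb
(cis-regulation), recording the number of overlapped grid positions
("window count") as the length proxy -- score opportunity grows with the
number of maximised positions, not with bp length per se.  Genes are
standardised within 20 equal-occupancy window-count bins.  The
location/scale pair is median/MAD (SD-consistent) rather than mean/SD:
under the null the two coincide, but when sweeps occupy a non-negligible
fraction of a bin -- as in simulated genomes where every 5-Mb chromosome
carries a planted sweep, where footprints cover ~20% of genes -- moment
estimates absorb the signal into the bin scale and destroy power, while
the robust pair does not.  A rank-based variant is available
(`method = "rank"`) but caps attainable significance at roughly the
reciprocal bin size and is not the default.  One-sided upper-tail normal
P-values (sweeps only inflate the CLR) receive Storey q-values with
$\pi_0$ estimated at fixed $\lambda = 0.5$ (no spline, for determinism
and small-m robustness).

Candidate regions are built at a permissive $q < 0.1$, collapsing
outlier genes whose midpoints lie within 1 Mb (single linkage, per
population), merging clusters across populations that share a gene
(transitive closure), and finally keeping regions with at least one gene
at $q < 0.01$ in a powered, in-scope population.  Presence per population
uses $q < 0.05$ on member genes.  Sweep antiquity is classified against a
reference-sample panel by diagnostic-allele matching (a sample carries
the sweep if it covers at least half the diagnostic sites and matches at
least 90% of the covered ones; the oldest carrying sample sets the age
class, with non-carriers pooled into the youngest class): this is an
explicit quantitative stand-in for manual haplotype inspection, with both
thresholds configurable.  Presence-by-group differences are tested with a
Bernoulli likelihood-ratio test using closed-form group MLEs (exact at
boundary separation, where `glm` fails) against a chi-square with
$G - 1$ df.

# Divergence tests

Per-SNP $F_{st}$ against an outgroup uses the haploid two-population
Weir-Cockerham ANOVA form
$\theta = (MSA - MSW)/(MSA + (n_c - 1)\,MSW)$ -- pseudohaploid calls are
haploid draws, so no heterozygosity term applies.  Outlier detection fits
a scaled chi-square (unknown df and mean) to the central 90% of positive
$F_{st}$ values at expected heterozygosity $\ge 0.1$, by maximum
likelihood with the trimmed-mass renormalisation; right-tail P-values
get Storey q-values.  This is a deliberately simplified single-stratum
variant of the chi-square-fit outlier method used for such scans.
Region-level elevation uses a one-sided rank-sum test with tie and
continuity corrections (fully tied input returns exactly 0.5, where the
standard implementation is undefined).

# The simulation engine

## Model and rationale

Replicates are 5-Mb regions evolved through a multi-branch demography
with splits, admixture pulses and additive selection ($h = 0.5$) at a
mid-region site, at mutation and recombination rates of $10^{-8}$ per bp
per generation and generation time 29 years.  The engine factorises the
problem: the selected locus is simulated exactly (diploid
Wright-Fisher per branch, establishment-conditioned by resampling until
the beneficial allele reaches frequency 0.10), and every neutral site is
then advanced as a two-locus system conditioned on that trajectory --
derived counts on the beneficial and wild backgrounds with structured
binomial transitions and recombination mixing at rate $r\,d$ per meiosis.
Every statistic the package computes (composite likelihood, SFS, gene
scores, $F_{st}$) is a functional of per-site marginals, which this
factorisation reproduces; what it does not represent is linkage
disequilibrium among neutral sites, so haplotype-based statistics (EHH
and relatives) cannot be computed from its output.  Sampled individuals
do share a replicate-level beneficial-background draw, so partial sweeps
produce coherent cross-site signal in the sample.

Sites are initialised from the stationary neutral spectrum of the root
population (counts drawn proportional to $1/j$), truncated at minor
allele frequency 0.02.  Post-initialisation mutation influx is available
(`new_mutations = TRUE`, the default, required for long neutral
equilibrium runs) but is disabled in the shipped experiment
configurations: the heterozygosity-panel ascertainment retains a variant
arising within the simulated window (a few hundred generations) with
probability of order $8/(2N)$ per copy, and the 2,000-variant
downsampling discards most of what remains, so the influx contributes
essentially nothing to the analysed data while dominating runtime.
Rescaling by $\lambda$ maps $N_e \to N_e/\lambda$, times
$\to$ times$/\lambda$, and $\{s, \mu, r\} \to \lambda\{s, \mu, r\}$,
preserving $4N_e\mu$, $4N_e r$ and $N_e s$; the admixture experiments run
at $\lambda = 10$.

## The West Eurasian demography

The bundled model (`west_eurasian_model()`, parameter tables in
`inst/extdata/`) reconstructs West Eurasian history from its published
anchors: a 12-fold out-of-Africa founding bottleneck (22,800 to 1,900
diploids, 65-55 ka), a Main Eurasian branch at $N_e = 12{,}000$
(consistent with sweep-signal persistence of $0.2 N_e$ generations
$\approx$ 70 kyr), a WHG branch with a further 6-fold reduction to 2,000
($\approx$ 11 kyr persistence), a Steppe-ancestor branch
($N_e = 6{,}000$, split 45 ka), a 50% WHG pulse into the Main branch at
8 ka and a 33% Steppe pulse at 4.5 ka.  Split times are constrained by
the scenario design: beneficial mutations introduced at 55, 44 and 36 ka
respectively predate all splits, postdate the Steppe-lineage separation,
and postdate the WHG separation.  The African branch exists to supply the
two African ascertainment-panel diploids.  Sample sizes and times follow
the empirical configuration (Anatolian EF 28 at 8.5 ka, WHG 45 at
8.5 ka, Steppe 68 at 5 ka, European EF 78 at 7 ka, LNBA 192 at 4 ka,
Modern Europeans 200 at present, interpreted as pseudohaploid call
counts).  These tables are data, not code, and are the editable
reproduction target.

## Ancient-DNA artifacts

Sampled diploids are pseudohaploidised (one allele per individual per
site), thinned by site-specific missingness (rates resampled from an
empirical vector when supplied, else Beta(0.5, 2) truncated at 0.9),
ascertained on a 2 African + 2 European diploid heterozygosity panel
(emulating SNP-capture ascertainment, which depletes rare variants), and
downsampled to 2,000 variants per 5-Mb region.  The neutral mutation
supply is halved in the admixture experiments
(`neutral_mu_factor = 0.5`), which still leaves roughly twice the
2,000-variant target after ascertainment while halving runtime; the
constant-size experiments keep the full supply.

## What passing tests do and do not show

The simulator reproduces per-site frequency dynamics (martingale
behaviour, equilibrium diversity $4N_e\mu$ with influx enabled, pulse
ancestry fractions, diffusion establishment probabilities) and the
artifact layer's marginal effects (fair pseudohaploid draws, singleton
depletion under ascertainment).  Because neutral cross-site LD is not
modelled, agreement here validates SFS-based inference only; conclusions
about haplotype-statistic behaviour on real data are outside what these
tests can establish.

# Power, FDR and the admixture experiments

Detection thresholds are the empirical $1 - FPR$ quantile (type-7) of
per-replicate maximum CLR over at least 1,000 neutral replicates run
through the identical pipeline; the same neutral set supplies the
background spectrum.  Power is the fraction of 200
establishment-conditioned selection replicates exceeding the threshold,
with Wilson 95% intervals.  Study-scale FDR tiles independent neutral
regions into genomes, runs the full gene-score and two-tier region
pipeline, and reports $\bar{FP}/(\bar{FP} + D)$ with the discovery count
$D$ supplied (default 57).

Two headline behaviours are reproduced at these settings: (i) a
beneficial mutation arising at 44 ka with $s = 0.1$ and selection
persisting through both admixture pulses re-fixes in Modern Europeans
and is detected with power well above 65% at FPR 0.1%; (ii) sweeps
stopped when the beneficial haplotype first reaches 80% frequency are
detected in under half of replicates, and with selection ceasing at the
8-ka pulse only sweeps predating the Eurasian diversification (55 ka)
remain detectable in admixed moderns, while 36-ka sweeps (diluted to
about one-third frequency) vanish.

# Sweep-origin theory

With an environmental shift that triggers beneficial selection $s_b$
(previously deleterious $s_d$, both $h = 0.5$) and a bottleneck from
$N_e$ to $N_{post}$, the standing-variant rescue probability follows the
classical diffusion result
$P_{sgv} = 1 - (1 + \alpha_b/\alpha_d)^{-\Theta}$ with
$\Theta = 4N_e\mu L$, $\alpha_b = 2N_{post}s_b$ and
$\alpha_d = 2N_e s_d$.  De novo rescue arises as a Poisson process of
destined-to-fix copies at rate $2N_{post}\mu L\,\pi(s_b)$ per
generation, $\pi(s) = (1 - e^{-s})/(1 - e^{-2Ns})$, over a usable window
equal to the fixation window minus the expected fixation lag
$2\ln(2N_{post}s_b)/s_b$ generations (switchable; at $s_b = 0.01$ a
sweep takes tens of kyr to complete, so "fixation within $T$" is
necessarily an establishment-based statement).  The two origins combine
by rescue precedence -- standing variants, being already established,
pre-empt de novo origins:
$R = P_{sgv} / (P_{sgv} + (1 - P_{sgv})P_{dn})$.

Hardness (a single-origin signature) is closed-form for de novo sweeps
($\lambda e^{-\lambda}/(1 - e^{-\lambda})$ for Poisson origins).  For
standing variation, hardness counts *standing copies*: even a
single-origin allele standing at frequency $x$ contributes $\sim 2Nx$
distinct haplotypes, so the small-$\Theta$ limit is below one -- unlike
the de novo case.  The textbook independent-establishment count
(Poisson with mean $2N_{post}\pi x$) ignores lineage pruning during the
sweep itself, which we measured at 8 Monte-Carlo standard errors against
the exact process in the reference regime, with a deficit that grows
with $N s$; the package therefore computes SGV hardness by a reduced
conditional simulation -- standing frequency drawn from the analytic
density $\Theta x^{\Theta-1}e^{-\alpha_d x}$, each copy surviving the
bottleneck tagged, and the beneficial class run to fixation exactly --
under an internal fixed random stream (deterministic output, Monte-Carlo
SE about 0.01).  The fully independent `wf_origin_oracle()` -- explicit
deleterious phase with recurrent mutation, bottleneck, origin-tagged
beneficial phase -- validates every component to within 3 Monte-Carlo
standard errors across a parameter grid in the test suite.

```{r theory-example}
p <- theory_params()  # Ne 10,000 -> 1,000; s_b 0.01; s_d 0.001; T 20 kyr
c(P_sgv = p_fix_window_sgv(p),
  P_denovo = p_fix_window_denovo(p),
  R_sgv = sgv_relative_probability(p),
  hard_sgv = hard_sweep_probability(p, "sgv"),
  hard_denovo = hard_sweep_probability(p, "denovo"))
```

# Auxiliary calculators

Selection strength from a fitted intensity is
$\hat{s} = r\ln(2N_e)/\hat\alpha$ (robust to $N_e$ through the
logarithm; default $N_e = 10^4$); the sweep signal persists for about
$0.2\,N_e$ generations ($\approx 70$ kyr on the Main Eurasian branch,
$\approx 11$ kyr in WHG).  The expected diversity trough across a
completed sweep under a recombination map is
$H(x)/H_0 = 1 - (1 - p_e)^2$ with
$p_e = 1 - \exp(-\ln(2N_e)/s \cdot G(x))$ and $G$ the genetic distance
(Morgans) to the sweep centre -- on a uniform map this reduces exactly
to the escape-probability profile at $\alpha = r\ln(2N_e)/s$.

# Problem sizes and reproducibility

The shipped experiment configurations use $\lambda = 10$, 5-Mb regions,
1,000 neutral and 200 selection replicates per scenario, 5-kb scan grids
and a 2-Mb inclusion radius; the constant-size planted-sweep experiments
run unscaled ($\lambda = 1$) because their horizon is a few hundred
generations.  All randomness flows through R's RNG (a single seed
reproduces replicates bit-exactly), except the SGV hardness calculator's
internal fixed stream, which restores the caller's RNG state.

# Known limitations

* No neutral cross-site LD: haplotype statistics are out of reach by
  design.
* The demography tables are a reconstruction from printed anchors, not a
  fitted model; absolute power numbers inherit their uncertainty.
* The chi-square outlier fit uses a single sample-size stratum with a
  fixed 5% trim.
* Diagnostic-allele sweep dating is a stand-in for manual haplotype
  inspection; individual sweep dates are coarse.
* Background selection, non-additive dominance and the X chromosome are
  not modelled.
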