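## Closed-form sweep calculators: selection strength from the composite
## intensity, signal persistence, the expected diversity trough under a
## recombination map, and standing-variation versus de novo origin
## probabilities with single-origin (hardness) probabilities, each validated
## against the bundled Wright-Fisher Monte-Carlo oracle.

#' Parameter set for the sweep-origin theory
#'
#' @param Ne ancestral diploid effective size.
#' @param g generation time in years (default 29).
#' @param mu per-bp per-generation mutation rate (default 1.25e-8).
#' @param L mutational target size in sites.
#' @param s_b beneficial selection coefficient (h = 0.5).
#' @param s_d deleterious coefficient acting on the allele before the
#'   environmental shift (h = 0.5).
#' @param T_years fixation window in years.
#' @param bottleneck_factor population-size divisor at the shift
#'   (default 10; post-shift size `Ne / bottleneck_factor`).
#' @param subtract_lag subtract the expected fixation lag
#'   \eqn{2 \ln(2 N_{post} s_b)/s_b} generations from the de novo window
#'   (default TRUE).
#' @return list of validated parameters (class `theory_params`).
#' @export
theory_params <- function(Ne = 10000, g = 29, mu = 1.25e-8, L = 1000,
                          s_b = 0.01, s_d = 0.001, T_years = 20000,
                          bottleneck_factor = 10, subtract_lag = TRUE) {
  stopifnot(Ne > 0, g > 0, mu >= 0, L > 0, s_b > 0, s_d >= 0, T_years >= 0,
            bottleneck_factor >= 1)
  structure(list(Ne = Ne, g = g, mu = mu, L = L, s_b = s_b, s_d = s_d,
                 T_years = T_years, bottleneck_factor = bottleneck_factor,
                 N_post = Ne / bottleneck_factor,
                 subtract_lag = subtract_lag),
            class = "theory_params")
}

#' Establishment (ultimate fixation) probability of a single new copy
#'
#' Diffusion result for additive selection (fitnesses 1, 1 + s/2, 1 + s):
#' \eqn{\pi = (1 - e^{-s}) / (1 - e^{-2 N s})}.
#' @param s_b selection coefficient.
#' @param N diploid population size.
#' @export
establishment_prob <- function(s_b, N) {
  if (s_b == 0) return(1 / (2 * N))
  -expm1(-s_b) / -expm1(-2 * N * s_b)
}

#' Selection strength from the composite sweep intensity
#'
#' \eqn{\hat s = r \ln(2 N_e) / \hat\alpha}; robust to `Ne` through the
#' logarithm.
#' @param alpha_hat fitted sweep intensity (per bp).
#' @param r local recombination rate (per bp per generation).
#' @param Ne effective population size (default 10,000).
#' @export
selection_strength <- function(alpha_hat, r, Ne = 10000) {
  if (any(alpha_hat <= 0) || any(r <= 0) || any(Ne <= 0))
    stop("all inputs must be > 0")
  r * log(2 * Ne) / alpha_hat
}

#' Expected sweep-signal persistence time
#'
#' Hard-sweep SFS distortion decays within about `0.2 Ne` generations;
#' returns that horizon in years.
#' @param Ne diploid effective size.
#' @param g generation time in years (default 29).
#' @export
signal_loss_time <- function(Ne, g = 29) {
  if (any(Ne <= 0) || any(g <= 0)) stop("Ne and g must be > 0")
  0.2 * Ne * g
}

#' Expected relative diversity across a completed hard sweep
#'
#' Pairwise-coalescence approximation: with genetic distance `G(x)`
#' (Morgans) between position `x` and the sweep centre,
#' \eqn{p_e(x) = 1 - \exp(-\ln(2 N_e)/s \cdot G(x))} and
#' \eqn{H(x)/H_0 = 1 - (1 - p_e)^2}.
#'
#' @param map recombination map for the chromosome
#'   (see [read_recombination_map()]).
#' @param center sweep position (bp; must lie within the map span).
#' @param s selection coefficient (> 0).
#' @param Ne effective population size.
#' @param positions positions at which to evaluate (default: map positions).
#' @return data.frame `pos`, `rel_diversity`.
#' @export
diversity_profile <- function(map, center, s, Ne, positions = map$pos) {
  if (s <= 0) stop("s must be > 0")
  if (center < min(map$pos) || center > max(map$pos))
    stop("center outside map span")
  G <- abs(genetic_position(map, positions) - genetic_position(map, center))
  pe <- -expm1(-log(2 * Ne) / s * G)
  data.frame(pos = positions, rel_diversity = 1 - (1 - pe)^2)
}

## de novo usable window in generations (window minus expected fixation lag)
.usable_window <- function(params) {
  T_gen <- params$T_years / params$g
  if (!params$subtract_lag) return(T_gen)
  lag <- 2 * log(2 * params$N_post * params$s_b) / params$s_b
  if (!is.finite(lag) || lag < 0) lag <- 0
  if (lag >= T_gen) {
    warning("fixation window shorter than the expected fixation lag")
    return(0)
  }
  T_gen - lag
}

#' Probability of a completed de novo sweep within the fixation window
#'
#' Destined-to-fix de novo copies arise as a Poisson process with rate
#' \eqn{2 N_{post} \mu L \pi(s_b)} per generation over the usable window
#' (the window minus the expected fixation lag; see vignette), giving
#' \eqn{P = 1 - e^{-\lambda T_{use}}}.
#'
#' @param params a [theory_params()].
#' @export
p_fix_window_denovo <- function(params) {
  Tu <- .usable_window(params)
  lam <- 2 * params$N_post * params$mu * params$L *
    establishment_prob(params$s_b, params$N_post)
  -expm1(-lam * Tu)
}

#' Probability of a sweep from standing genetic variation
#'
#' Standing-variant rescue probability: with the allele frequency at the
#' shift drawn from mutation-selection-drift balance at the ancestral size
#' under `s_d`, and fixation under `s_b` at the post-bottleneck size,
#' \eqn{P_{sgv} = 1 - (1 + \alpha_b/\alpha_d)^{-\Theta}} with
#' \eqn{\Theta = 4 N_e \mu L}, \eqn{\alpha_b = 2 N_{post} s_b},
#' \eqn{\alpha_d = 2 N_e s_d}.
#'
#' @param params a [theory_params()].
#' @export
p_fix_window_sgv <- function(params) {
  theta <- 4 * params$Ne * params$mu * params$L
  if (theta == 0) return(0)
  a_b <- 2 * params$N_post * params$s_b
  a_d <- 2 * params$Ne * params$s_d
  if (!is.finite(a_d) || a_d == Inf) return(0)
  if (a_d <= 0) a_d <- 1 # s_d = 0: neutral standing alleles; see vignette
  -expm1(-theta * log1p(a_b / a_d))
}

#' Relative probability that a sweep arose from standing variation
#'
#' Rescue-precedence combination: standing variants, if destined to fix,
#' pre-empt de novo origins, so
#' \eqn{R = P_{sgv} / (P_{sgv} + (1 - P_{sgv}) P_{dn})}.
#'
#' @param params a [theory_params()].
#' @return probability in `[0, 1]`, or `NA` if both components are zero.
#' @export
sgv_relative_probability <- function(params) {
  ps <- p_fix_window_sgv(params)
  pd <- p_fix_window_denovo(params)
  den <- ps + (1 - ps) * pd
  if (den == 0) return(NA_real_)
  ps / den
}

#' Probability that a completed sweep is hard (single origin)
#'
#' For de novo origins the computation is closed-form: successful origins
#' in the usable window are Poisson(\eqn{\lambda}), so
#' \eqn{P = \lambda e^{-\lambda} / (1 - e^{-\lambda})}.  For standing
#' variation the probability that all fixing copies descend from a single
#' standing haplotype is computed by a reduced conditional simulation: the
#' allele frequency at the shift is drawn from the analytic mutation-
#' selection-drift density \eqn{\Theta x^{\Theta-1} e^{-\alpha_d x}}, each
#' copy surviving the bottleneck is tagged, and the beneficial class is run
#' to fixation exactly (the fully independent-copy closed form ignores
#' within-sweep lineage pruning and overstates softness; see vignette).
#' The reduced computation uses an internal fixed random stream, so the
#' result is deterministic (Monte-Carlo standard error about 0.01 at the
#' default `n_sim`); the explicit-phase [wf_origin_oracle()] is its
#' independent check.
#'
#' @param params a [theory_params()].
#' @param origin `"sgv"` or `"denovo"`.
#' @param n_sim replicates of the reduced computation (SGV origin only).
#' @export
hard_sweep_probability <- function(params, origin = c("sgv", "denovo"),
                                   n_sim = 6000) {
  origin <- match.arg(origin)
  if (origin == "denovo") {
    Tu <- .usable_window(params)
    lam <- 2 * params$N_post * params$mu * params$L *
      establishment_prob(params$s_b, params$N_post) * Tu
    if (lam == 0) return(1)
    return(lam * exp(-lam) / -expm1(-lam))
  }
  theta <- 4 * params$Ne * params$mu * params$L
  if (theta == 0) return(1)  # single origin forced as Theta -> 0
  a_d <- 2 * params$Ne * params$s_d
  seed_state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(seed_state))
    assign(".Random.seed", seed_state, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv))
  set.seed(424243L)
  res <- .wf_hard_sgv_reduced(as.integer(round(2 * params$N_post)),
                              params$s_b, theta, a_d,
                              0.1 / (2 * params$Ne), as.integer(n_sim),
                              200000L)
  if (res$n_fixed == 0) return(NA_real_)
  res$p_hard
}

#' Wright-Fisher Monte-Carlo oracle for the sweep-origin probabilities
#'
#' Discrete WF simulation with additive selection, recurrent one-way
#' mutation at rate `mu * L`, deleterious selection `s_d` before the
#' environmental shift, a bottleneck at the shift and beneficial selection
#' `s_b` after it, with origin/copy tagging.  Components are isolated to
#' match the closed-form event definitions: the de novo path restricts
#' mutational input to the usable window and runs to fixation/loss with no
#' standing variation; the standing path simulates the deleterious phase
#' explicitly, tags every copy surviving the bottleneck and runs the
#' beneficial phase without further input.
#'
#' @param params a [theory_params()].
#' @param n_replicates Monte-Carlo replicates (>= 1000 for CI reporting).
#' @param burn_gens deleterious-phase burn-in (default `20 / s_d` capped to
#'   `4 Ne`).
#' @param seed optional integer seed (`set.seed` is called if given).
#' @return list with component estimates and binomial standard errors.
#' @export
wf_origin_oracle <- function(params, n_replicates = 10000, burn_gens = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_replicates < 1000)
    warning("fewer than 1000 replicates: intervals will be unreliable")
  twoN_anc <- round(2 * params$Ne)
  twoN_post <- round(2 * params$N_post)
  muL <- params$mu * params$L
  Tu <- ceiling(.usable_window(params))
  if (is.null(burn_gens))
    burn_gens <- as.integer(min(4 * params$Ne,
                                max(2000, ceiling(20 / max(params$s_d,
                                                           1e-4)))))
  dn <- .wf_oracle_denovo(twoN_post, params$s_b, muL, as.integer(Tu),
                          as.integer(n_replicates), 200000L)
  sg <- .wf_oracle_sgv(twoN_anc, twoN_post, params$s_d, params$s_b, muL,
                       as.integer(burn_gens), as.integer(n_replicates),
                       200000L)
  list(p_denovo = dn$p_fix, se_denovo = dn$se_fix,
       p_hard_denovo = dn$p_hard, se_hard_denovo = dn$se_hard,
       p_sgv = sg$p_fix, se_sgv = sg$se_fix,
       p_hard_sgv = sg$p_hard, se_hard_sgv = sg$se_hard,
       mean_standing_post = sg$mean_standing_post,
       n_fixed = sg$n_fixed,
       n_replicates = n_replicates, burn_gens = burn_gens,
       usable_window_gen = Tu)
}
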