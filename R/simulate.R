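## Forward simulation of 5-Mb regions under a multi-branch demography with
## admixture pulses and additive selection, plus the ancient-DNA artifact
## layer (pseudohaploidisation, site-specific missingness, heterozygosity-
## panel ascertainment, variant downsampling) and neutral-background
## generation.  The engine simulates the selected locus exactly and every
## neutral site as a two-locus system conditioned on the selected-locus
## trajectory (see the methods vignette).

#' Demographic model
#'
#' @param branches data.frame `name`, `Ne` (diploid), `start_ka`, `end_ka`
#'   (years BP / 1000; start > end), `parent` (NA for the root).
#' @param pulses data.frame `time_ka`, `source`, `dest`, `fraction`.
#' @param samples data.frame `population`, `branch`, `time_ka`, `n`
#'   (pseudohaploid sample counts).
#' @param generation_time years per generation (default 29).
#' @param panel_branches named list with `afr` and `eur`: branches supplying
#'   the 2 + 2 diploid ascertainment panel (sampled at the most recent
#'   common sampling time of the branch).
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(branches, pulses = NULL, samples = NULL,
                              generation_time = 29,
                              panel_branches = NULL) {
  stopifnot(is.data.frame(branches))
  if (sum(is.na(branches$parent)) != 1) stop("exactly one root branch")
  if (is.null(pulses))
    pulses <- data.frame(time_ka = numeric(0), source = character(0),
                         dest = character(0), fraction = numeric(0))
  if (any(pulses$fraction <= 0 | pulses$fraction >= 1))
    stop("pulse fractions must be in (0, 1)")
  for (i in seq_len(nrow(pulses))) {
    for (nm in c(pulses$source[i], pulses$dest[i])) {
      b <- branches[branches$name == nm, ]
      if (nrow(b) != 1) stop("pulse references unknown branch ", nm)
      if (pulses$time_ka[i] > b$start_ka || pulses$time_ka[i] < b$end_ka)
        stop("pulse at ", pulses$time_ka[i], " ka outside lifespan of ", nm)
    }
  }
  structure(list(branches = branches, pulses = pulses, samples = samples,
                 generation_time = generation_time,
                 panel_branches = panel_branches),
            class = "demographic_model")
}

#' Bundled West Eurasian demographic model
#'
#' Six-branch reconstruction of West Eurasian population history: an
#' African/ancestral lineage (Ne 22,800), a 12-fold out-of-Africa founding
#' bottleneck (Ne 1,900, 65-55 ka), a Main Eurasian branch (Ne 12,000)
#' carrying the Anatolian-farmer ancestry to the present, a Steppe-ancestor
#' branch (Ne 6,000, split 45 ka) and a Western Hunter-Gatherer branch with
#' a further 6-fold reduction (Ne 2,000, split 40 ka), with a 50% WHG pulse
#' into the Main branch at 8 ka and a 33% Steppe pulse at 4.5 ka.  Sample
#' configuration: Anatolian EF n = 28 at 8.5 ka, WHG n = 45 at 8.5 ka,
#' Steppe n = 68 at 5 ka, European EF n = 78 at 7 ka, LNBA n = 192 at 4 ka
#' and Modern Europeans n = 200 at present.  The parameter tables ship as
#' editable data in `inst/extdata`.
#'
#' @return a [demographic_model()].
#' @export
west_eurasian_model <- function() {
  pth <- function(f) system.file("extdata", f, package = "paleosweep",
                                 mustWork = TRUE)
  br <- utils::read.table(pth("west_eurasian_branches.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  pu <- utils::read.table(pth("west_eurasian_pulses.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  sa <- utils::read.table(pth("west_eurasian_samples.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  demographic_model(br, pu, sa,
                    panel_branches = list(afr = "AFR", eur = "MAIN"))
}

#' Constant-size single-population model
#'
#' @param Ne diploid size.
#' @param duration_ka simulated span in ka.
#' @param n sample size (pseudohaploid calls) at time 0.
#' @export
constant_model <- function(Ne = 10000, duration_ka = 5, n = 50) {
  br <- data.frame(name = "POP", Ne = Ne, start_ka = duration_ka,
                   end_ka = 0, parent = NA_character_,
                   stringsAsFactors = FALSE)
  sa <- data.frame(population = "POP", branch = "POP", time_ka = 0, n = n,
                   stringsAsFactors = FALSE)
  demographic_model(br, samples = sa,
                    panel_branches = list(afr = "POP", eur = "POP"))
}

#' Selection specification
#'
#' @param onset_ka onset of positive selection in ka BP (introduction time
#'   of the single beneficial mutation).
#' @param s selection coefficient (> 0; additive, h = 0.5).
#' @param cessation_ka time at which selection ceases (NULL: never).
#' @param branch branch on which the mutation arises (default `"MAIN"`).
#' @param position bp position (default: region midpoint; NA defers).
#' @export
selection_spec <- function(onset_ka, s, cessation_ka = NULL,
                           branch = "MAIN", position = NA) {
  stopifnot(s > 0)
  if (!is.null(cessation_ka) && cessation_ka > onset_ka)
    stop("cessation must not precede onset")
  structure(list(onset_ka = onset_ka, s = s, cessation_ka = cessation_ka,
                 branch = branch, position = position),
            class = "selection_spec")
}

#' Ancient-DNA artifact specification
#'
#' @param pseudohaploid draw a single allele per individual per site.
#' @param missing_rates optional empirical per-site missing-rate vector
#'   (resampled with replacement); otherwise rates are Beta(`beta_a`,
#'   `beta_b`) truncated to `[0, missing_max]`.
#' @param beta_a,beta_b,missing_max Beta missingness model parameters.
#' @param ascertain retain only sites heterozygous in at least one of the
#'   two African panel diploids or at least one of the two European panel
#'   diploids.
#' @param target_variants downsample surviving variants to this many sites
#'   (default 2,000 per 5-Mb region; all kept, with a warning, if fewer
#'   survive).
#' @export
artifact_spec <- function(pseudohaploid = TRUE, missing_rates = NULL,
                          beta_a = 0.5, beta_b = 2, missing_max = 0.9,
                          ascertain = TRUE, target_variants = 2000L) {
  stopifnot(target_variants >= 1)
  if (!is.null(missing_rates) &&
      any(missing_rates < 0 | missing_rates > 1))
    stop("missing rates must be in [0, 1]")
  structure(list(pseudohaploid = pseudohaploid,
                 missing_rates = missing_rates, beta_a = beta_a,
                 beta_b = beta_b, missing_max = missing_max,
                 ascertain = ascertain,
                 target_variants = as.integer(target_variants)),
            class = "artifact_spec")
}

#' Rescale a simulation configuration
#'
#' Standard population-genetic rescaling by `lambda`: sizes and times are
#' divided by `lambda`; `s`, `mu` and `r` are multiplied by it, preserving
#' `4 Ne mu`, `4 Ne r` and `Ne s`.
#'
#' @param model a [demographic_model()].
#' @param selection optional [selection_spec()].
#' @param mu,r per-bp per-generation rates.
#' @param lambda scaling factor (>= 1).
#' @return list `model`, `selection`, `mu`, `r`, `lambda` with scaled values.
#' @export
rescale <- function(model, selection = NULL, mu = 1e-8, r = 1e-8,
                    lambda = 1) {
  stopifnot(lambda >= 1)
  m <- model
  m$branches$Ne <- m$branches$Ne / lambda
  m$branches$start_ka <- m$branches$start_ka / lambda
  m$branches$end_ka <- m$branches$end_ka / lambda
  m$pulses$time_ka <- m$pulses$time_ka / lambda
  if (!is.null(m$samples)) m$samples$time_ka <- m$samples$time_ka / lambda
  sel <- selection
  if (!is.null(sel)) {
    sel$onset_ka <- sel$onset_ka / lambda
    if (!is.null(sel$cessation_ka))
      sel$cessation_ka <- sel$cessation_ka / lambda
    sel$s <- sel$s * lambda
  }
  list(model = m, selection = sel, mu = mu * lambda, r = r * lambda,
       lambda = lambda)
}

## compile a model to engine arrays at scaling lambda
.compile_model <- function(model, lambda) {
  br <- model$branches
  g <- model$generation_time
  root_ka <- max(br$start_ka)
  gen_of <- function(t_ka) as.integer(round((root_ka - t_ka) * 1000 /
                                              (lambda * g)))
  ord <- order(is.na(br$parent), decreasing = TRUE) # root first
  br <- br[ord, ]
  ## ensure parents precede children
  repeat {
    pi <- match(br$parent, br$name)
    bad <- which(!is.na(pi) & pi > seq_len(nrow(br)))
    if (!length(bad)) break
    i <- bad[1]
    br <- br[append(seq_len(nrow(br))[-i], i, after = pi[i] - 1), ]
  }
  idx <- stats::setNames(seq_len(nrow(br)) - 1L, br$name)
  list(names = br$name,
       parent = ifelse(is.na(br$parent), -1L, idx[br$parent]),
       start = gen_of(br$start_ka), end = gen_of(br$end_ka),
       twoN = as.integer(pmax(4, round(2 * br$Ne / lambda))),
       pulse_gen = gen_of(model$pulses$time_ka),
       pulse_src = as.integer(idx[model$pulses$source]),
       pulse_dst = as.integer(idx[model$pulses$dest]),
       pulse_frac = model$pulses$fraction,
       gen_of = gen_of, idx = idx, root_ka = root_ka)
}

## stationary neutral registry: sites drawn from the 1/j spectrum of the
## root population, truncated at minor allele frequency init_min_maf
.init_registry <- function(twoN_root, theta_L, region_bp, init_min_maf) {
  jmin <- max(1L, ceiling(init_min_maf * twoN_root))
  j <- jmin:(twoN_root - jmin)
  w <- 1 / j
  S <- stats::rpois(1, theta_L * sum(w))
  if (S == 0) S <- 1
  counts <- j[sample.int(length(j), S, replace = TRUE, prob = w)]
  pos <- sort(stats::runif(S, 1, region_bp))
  list(pos = pos, x0 = as.integer(counts))
}

#' Simulate one region replicate
#'
#' Wright-Fisher simulation of a `region_bp` region through `model`, with
#' an optional beneficial mutation introduced as a single copy (mid-region
#' by default) and establishment conditioning.  Returns raw sampled
#' haplotypes per population (2n rows per population of n individuals),
#' the ascertainment-panel haplotypes, per-branch beneficial trajectories
#' and a truth record.
#'
#' @param model a [demographic_model()].
#' @param selection a [selection_spec()] or NULL (neutral).
#' @param region_bp region length (default 5 Mb).
#' @param mu,r unscaled per-bp per-generation mutation and recombination
#'   rates (default 1e-8 each).
#' @param lambda rescaling factor (default 1).
#' @param neutral_mu_factor fraction of the neutral mutation supply that is
#'   simulated (the ascertainment and 2,000-variant downsampling make the
#'   full supply redundant; see vignette).
#' @param init_min_maf minor-allele-frequency truncation of the stationary
#'   initial registry.
#' @param new_mutations simulate post-initialisation neutral mutation
#'   influx (TRUE for equilibrium fidelity; the shipped experiment configs
#'   disable it, see vignette).
#' @param condition_min_freq establishment condition: resample until the
#'   beneficial allele's maximum frequency reaches this (default 0.1 when
#'   selection is active).
#' @param stop_at_freq if set, stop the replicate when the beneficial
#'   allele first reaches this frequency on its branch and draw samples
#'   scheduled with `time_ka = NA` at that moment (partial-sweep designs).
#' @param max_tries conditioning attempt cap.
#' @param samples sampling design (default `model$samples`).
#' @param sample_panel draw the 2 + 2 diploid ascertainment panel.
#' @param ancestry_marker_branch optional branch name: adds one marker
#'   locus fixed in that branch at its founding (and absent elsewhere),
#'   whose frequency in descendants tracks that branch's ancestry fraction;
#'   its column index is returned as `marker_col`.
#' @return list with `populations` (per population a 0/1 haplotype matrix,
#'   2 rows per individual), `panel`, `positions`, `trajectories`
#'   (per-branch beneficial frequency paths), `truth`, `attempts`.
#' @export
simulate_replicate <- function(model, selection = NULL, region_bp = 5e6,
                               mu = 1e-8, r = 1e-8, lambda = 1,
                               neutral_mu_factor = 1,
                               init_min_maf = 0.02, new_mutations = TRUE,
                               condition_min_freq = 0.1,
                               stop_at_freq = NULL, max_tries = 10000L,
                               samples = model$samples,
                               sample_panel = TRUE,
                               ancestry_marker_branch = NULL) {
  cm <- .compile_model(model, lambda)
  mu_s <- mu * lambda * neutral_mu_factor
  r_s <- r * lambda
  twoN_root <- cm$twoN[1]
  theta_L <- 2 * twoN_root * mu_s * region_bp
  reg <- .init_registry(twoN_root, theta_L, region_bp, init_min_maf)
  fixb <- rep(-1L, length(reg$pos))
  marker_col <- NA_integer_
  if (!is.null(ancestry_marker_branch)) {
    ## extra locus fixed in one branch at its founding: tracks that branch's
    ## ancestry fraction in every admixed descendant
    reg$pos <- c(reg$pos, region_bp)
    reg$x0 <- c(reg$x0, 0L)
    fixb <- c(fixb, as.integer(cm$idx[[ancestry_marker_branch]]))
    marker_col <- length(reg$pos)
  }
  sel_active <- !is.null(selection)
  sel_pos <- region_bp / 2
  sel_branch <- 0L
  sel_intro <- 0L
  sel_cease <- -1L
  sel_s <- 0
  if (sel_active) {
    if (!is.na(selection$position)) sel_pos <- selection$position
    sel_branch <- cm$idx[[selection$branch]]
    sel_intro <- cm$gen_of(selection$onset_ka)
    if (!is.null(selection$cessation_ka))
      sel_cease <- cm$gen_of(selection$cessation_ka)
    sel_s <- selection$s * lambda
  }
  sa <- samples
  if (is.null(sa) || nrow(sa) == 0) stop("no sampling design")
  samp_branch <- as.integer(cm$idx[sa$branch])
  samp_gen <- ifelse(is.na(sa$time_ka), -1L, cm$gen_of(sa$time_ka))
  samp_nhap <- as.integer(2 * sa$n)
  labels <- sa$population
  if (sample_panel) {
    pb <- model$panel_branches
    if (is.null(pb)) stop("model lacks panel branches for ascertainment")
    for (nm in c("afr", "eur")) {
      b <- pb[[nm]]
      tka <- min(model$branches$end_ka[model$branches$name == b])
      samp_branch <- c(samp_branch, cm$idx[[b]])
      samp_gen <- c(samp_gen,
                    if (is.null(stop_at_freq)) cm$gen_of(tka) else -1L)
      samp_nhap <- c(samp_nhap, 4L)
      labels <- c(labels, paste0(".panel_", nm))
    }
  }
  res <- .wf_region_sim(cm$parent, cm$start, cm$end, cm$twoN,
                        cm$pulse_gen, cm$pulse_src, cm$pulse_dst,
                        cm$pulse_frac, sel_active, sel_branch, sel_intro,
                        sel_cease, sel_s, sel_pos, reg$pos,
                        as.integer(reg$x0), fixb, r_s, region_bp,
                        new_mutations, mu_s,
                        samp_branch, as.integer(samp_gen), samp_nhap,
                        if (sel_active) condition_min_freq else -1,
                        if (is.null(stop_at_freq)) -1 else stop_at_freq,
                        as.integer(max_tries))
  names(res$samples) <- labels
  names(res$sample_benef_freq) <- labels
  pops <- res$samples[!startsWith(labels, ".panel_")]
  panel <- list(afr = res$samples[[".panel_afr"]],
                eur = res$samples[[".panel_eur"]])
  trajs <- lapply(seq_along(cm$names), function(b)
    res$trajectories[[b]] / cm$twoN[b])
  names(trajs) <- cm$names
  list(populations = pops, panel = if (sample_panel) panel else NULL,
       positions = res$positions,
       trajectories = trajs,
       truth = list(sweep_position = if (sel_active) sel_pos else NA,
                    s = if (sel_active) selection$s else 0,
                    onset_ka = if (sel_active) selection$onset_ka else NA,
                    benef_freq = res$sample_benef_freq,
                    lambda = lambda),
       init_freq = reg$x0 / twoN_root, marker_col = marker_col,
       attempts = res$attempts, trigger_gen = res$trigger_gen,
       region_bp = region_bp)
}

#' Establishment conditioning for a replicate generator
#'
#' Draws replicates from `sim_fun` until the beneficial-allele trajectory's
#' maximum frequency reaches `min_freq`; reports the acceptance count.
#' ([simulate_replicate()] applies this internally; this wrapper serves
#' external generators.)
#'
#' @param sim_fun zero-argument function returning a replicate with a
#'   `trajectories` field.
#' @param min_freq establishment threshold (default 0.1).
#' @param max_tries attempt cap (abort below acceptance rate 1e-4).
#' @return accepted replicate with an `attempts` field.
#' @export
condition_establishment <- function(sim_fun, min_freq = 0.1,
                                    max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    rep <- sim_fun()
    maxf <- max(vapply(rep$trajectories, function(x)
      if (length(x)) max(x) else 0, 0))
    if (maxf >= min_freq) {
      rep$attempts <- i
      return(rep)
    }
  }
  stop("acceptance rate below ", format(1 / max_tries),
       ": establishment condition unattainable")
}

#' Apply ancient-DNA artifacts to sampled haplotypes
#'
#' Pseudohaploidisation (one allele drawn per individual per site),
#' site-specific missingness, heterozygosity-panel ascertainment (sites
#' heterozygous in at least one of two African or one of two European
#' panel diploids) and uniform downsampling to `target_variants` sites.
#'
#' @param haplotypes 0/1 matrix, two consecutive rows per individual.
#' @param positions site positions (bp).
#' @param artifact an [artifact_spec()].
#' @param panel list with `afr` and `eur` 4-row haplotype matrices (two
#'   diploids each); required when `artifact$ascertain`.
#' @param keep optional logical vector of pre-ascertained sites (shared
#'   across populations of one replicate); computed from `panel` if NULL.
#' @param folded polarisation flag written to the records: 1 (default)
#'   treats the data as reference-polarised without ancestral calls; 0
#'   marks the reference (simulated ancestral) allele as ancestral.
#' @return list `records` (chrom/position/x/n/folded/poly data.frame),
#'   `calls` (pseudohaploid matrix with NA missing), `positions`, `keep`.
#' @export
apply_adna_artifacts <- function(haplotypes, positions, artifact,
                                 panel = NULL, keep = NULL, folded = 1L) {
  n_ind <- nrow(haplotypes) / 2
  if (n_ind != floor(n_ind)) stop("haplotypes must pair into diploids")
  S <- ncol(haplotypes)
  if (is.null(keep)) {
    keep <- if (artifact$ascertain) {
      if (is.null(panel)) stop("ascertainment requires a panel")
      ascertain_sites(panel)
    } else rep(TRUE, S)
  }
  H <- haplotypes[, keep, drop = FALSE]
  pos <- positions[keep]
  ## pseudohaploid draw: one of the two chromosomes per individual per site
  odd <- seq(1, nrow(H), by = 2)
  if (artifact$pseudohaploid) {
    pick <- matrix(stats::runif(n_ind * ncol(H)) < 0.5, n_ind)
    calls <- H[odd, , drop = FALSE]
    even <- H[odd + 1, , drop = FALSE]
    calls[pick] <- even[pick]
  } else {
    calls <- H[odd, , drop = FALSE] + H[odd + 1, , drop = FALSE]
  }
  ## site-specific missingness
  m <- if (!is.null(artifact$missing_rates))
    sample(artifact$missing_rates, ncol(H), replace = TRUE)
  else pmin(artifact$missing_max,
            stats::rbeta(ncol(H), artifact$beta_a, artifact$beta_b))
  miss <- matrix(stats::runif(length(calls)), nrow(calls)) <
    rep(m, each = nrow(calls))
  calls[miss] <- NA_integer_
  ## downsample surviving variants
  n_var <- ncol(calls)
  if (n_var > artifact$target_variants) {
    sel <- sort(sample.int(n_var, artifact$target_variants))
    calls <- calls[, sel, drop = FALSE]
    pos <- pos[sel]
  } else if (n_var < artifact$target_variants) {
    warning(sprintf("only %d variants survive ascertainment (< %d): all kept",
                    n_var, artifact$target_variants))
  }
  n <- colSums(!is.na(calls))
  x <- colSums(calls, na.rm = TRUE)
  ok <- n > 0
  list(records = data.frame(chrom = "sim", position = pos[ok],
                            x = as.integer(x[ok]), n = as.integer(n[ok]),
                            folded = as.integer(folded),
                            poly = x[ok] > 0 & x[ok] < n[ok]),
       calls = calls, positions = pos, keep = keep)
}

#' Heterozygosity-panel site ascertainment
#'
#' @param panel list with `afr`, `eur`: 4-row haplotype matrices.
#' @return logical vector: site heterozygous in >= 1 African or >= 1
#'   European panel diploid.
#' @export
ascertain_sites <- function(panel) {
  het <- function(M) (M[1, ] != M[2, ]) | (M[3, ] != M[4, ])
  het(panel$afr) | het(panel$eur)
}

#' Neutral background spectra through the full simulation pipeline
#'
#' Simulates `n_replicates` neutral region replicates, applies the artifact
#' layer and pools the allele counts into one [background_sfs()] per
#' sampled population.
#'
#' @inheritParams simulate_replicate
#' @param n_replicates number of neutral replicates (default 1000).
#' @param artifact an [artifact_spec()].
#' @param seed optional seed.
#' @return named list of [background_sfs()] objects.
#' @export
neutral_background <- function(model, n_replicates = 1000,
                               artifact = artifact_spec(), region_bp = 5e6,
                               mu = 1e-8, r = 1e-8, lambda = 1,
                               neutral_mu_factor = 1,
                               new_mutations = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- list()
  for (i in seq_len(n_replicates)) {
    rep <- simulate_replicate(model, NULL, region_bp, mu, r, lambda,
                              neutral_mu_factor,
                              new_mutations = new_mutations)
    keep <- if (artifact$ascertain) ascertain_sites(rep$panel) else NULL
    for (pop in names(rep$populations)) {
      art <- apply_adna_artifacts(rep$populations[[pop]], rep$positions,
                                  artifact, rep$panel, keep)
      acc[[pop]] <- c(acc[[pop]], list(art$records))
    }
  }
  lapply(acc, function(recs) background_sfs(do.call(rbind, recs)))
}
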