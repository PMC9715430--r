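## Simulation experiment orchestration: detection thresholds at fixed false
## positive rate, power estimation by scenario, FDR estimation for the
## gene-level pipeline, and reproducible experiment runs.

#' Detection threshold at a fixed false positive rate
#'
#' Empirical `1 - fpr` quantile (type-7 interpolation) of neutral-replicate
#' maximum CLR values.
#'
#' @param neutral_max numeric vector of per-replicate max CLR under
#'   neutrality.
#' @param fpr target false positive rate (default 0.001).
#' @export
fpr_threshold <- function(neutral_max, fpr = 0.001) {
  if (length(neutral_max) == 0) stop("no neutral values")
  if (length(neutral_max) < 1000)
    warning("fewer than 1000 neutral replicates: threshold is noisy")
  unname(stats::quantile(neutral_max, 1 - fpr, type = 7))
}

#' Detection power with Wilson 95% confidence interval
#'
#' @param sel_max per-replicate max CLR under selection.
#' @param threshold detection threshold (from [fpr_threshold()]).
#' @return list `power`, `ci` (length 2), `n_replicates`, `threshold`.
#' @export
estimate_power <- function(sel_max, threshold) {
  n <- length(sel_max)
  if (n < 50) warning("fewer than 50 selection replicates")
  k <- sum(sel_max > threshold)
  p <- k / n
  z <- stats::qnorm(0.975)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(power = p, ci = c(max(0, ctr - hw), min(1, ctr + hw)),
       n_replicates = n, threshold = threshold)
}

## shared machinery: simulate a batch of replicates for one population,
## apply artifacts, return per-replicate records
.simulate_records <- function(model, selection, n_rep, population,
                              artifact, region_bp, mu, r, lambda,
                              neutral_mu_factor, stop_at_freq = NULL,
                              progress = FALSE) {
  out <- vector("list", n_rep)
  attempts <- integer(n_rep)
  benef <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    rep <- simulate_replicate(model, selection, region_bp, mu, r, lambda,
                              neutral_mu_factor, new_mutations = FALSE,
                              stop_at_freq = stop_at_freq)
    art <- apply_adna_artifacts(rep$populations[[population]],
                                rep$positions, artifact, rep$panel)
    out[[i]] <- art$records
    attempts[i] <- rep$attempts
    benef[i] <- rep$truth$benef_freq[[population]]
  }
  list(records = out, attempts = attempts, benef_freq = benef)
}

## max CLR per replicate against a fixed background
.max_clr <- function(records_list, bg, tables, grid, radius, alpha_grid) {
  vapply(records_list, function(rec) {
    tr <- suppressWarnings(clr_scan(rec, bg, grid, alpha_grid, radius,
                                    min_sites = 20L, tables = tables,
                                    refine_points = 8L))
    if (nrow(tr) == 0) 0 else max(tr$clr)
  }, 0)
}

#' Sweep detection power under the West Eurasian admixture model
#'
#' Full pipeline power experiment: neutral replicates define the background
#' SFS and the max-CLR null distribution; selection replicates (conditioned
#' on establishment) are scanned against the same background, and power is
#' the fraction exceeding the `fpr` threshold.
#'
#' @param onset_ka,s,cessation_ka selection scenario (see
#'   [selection_spec()]).
#' @param population sampled population under test.
#' @param n_sel,n_neutral replicate counts (defaults 200 and 1000).
#' @param lambda rescaling factor (default 10).
#' @param fpr false positive rate for the threshold (default 0.001).
#' @param model demographic model (default [west_eurasian_model()]).
#' @param artifact artifact layer (default [artifact_spec()]).
#' @param grid_step,radius scan grid spacing and site-inclusion radius (bp).
#' @param region_bp,mu,r region configuration.
#' @param neutral_mu_factor see [simulate_replicate()].
#' @param seed optional seed.
#' @param neutral_cache optional result of a previous run (reuses the
#'   neutral replicates, background and threshold).
#' @return list with `power`, `ci`, `threshold`, `neutral_max`, `sel_max`,
#'   `bg`, `mean_attempts`, `mean_final_freq`, and the scenario.
#' @export
power_experiment_admixture <- function(onset_ka = 44, s = 0.1,
                                       cessation_ka = NULL,
                                       population = "ModernEuropeans",
                                       n_sel = 200, n_neutral = 1000,
                                       lambda = 10, fpr = 0.001,
                                       model = west_eurasian_model(),
                                       artifact = artifact_spec(),
                                       grid_step = 5000, radius = 2e6,
                                       region_bp = 5e6, mu = 1e-8,
                                       r = 1e-8, neutral_mu_factor = 0.5,
                                       seed = NULL, neutral_cache = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model$samples <- model$samples[model$samples$population == population, ]
  grid <- seq(grid_step, region_bp, by = grid_step)
  if (is.null(neutral_cache)) {
    neu <- .simulate_records(model, NULL, n_neutral, population, artifact,
                             region_bp, mu, r, lambda, neutral_mu_factor)
    bg <- background_sfs(do.call(rbind, neu$records))
    tables <- clr_tables(bg)
    neutral_max <- .max_clr(neu$records, bg, tables, grid, radius,
                            alpha_grid_default())
  } else {
    bg <- neutral_cache$bg
    tables <- neutral_cache$tables
    neutral_max <- neutral_cache$neutral_max
  }
  threshold <- fpr_threshold(neutral_max, fpr)
  sel <- selection_spec(onset_ka, s, cessation_ka, branch = "MAIN")
  selr <- .simulate_records(model, sel, n_sel, population, artifact,
                            region_bp, mu, r, lambda, neutral_mu_factor)
  sel_max <- .max_clr(selr$records, bg, tables, grid, radius,
                      alpha_grid_default())
  pw <- estimate_power(sel_max, threshold)
  c(pw, list(neutral_max = neutral_max, sel_max = sel_max, bg = bg,
             tables = tables,
             mean_attempts = mean(selr$attempts),
             mean_final_freq = mean(selr$benef_freq),
             scenario = list(onset_ka = onset_ka, s = s,
                             cessation_ka = cessation_ka,
                             population = population, lambda = lambda,
                             fpr = fpr)))
}

#' Detection power for a partial sweep in a constant-size population
#'
#' Replicates stop when the beneficial allele first reaches `stop_freq`
#' and the population is sampled immediately; neutral replicates of the
#' same model calibrate the threshold.
#'
#' @param s selection coefficient.
#' @param Ne constant diploid size.
#' @param stop_freq sampling trigger frequency (default 0.80).
#' @param n_samples pseudohaploid genomes sampled (default 50).
#' @param neutral_gens neutral-replicate duration in (scaled) generations,
#'   chosen near the median sweep stopping time.
#' @inheritParams power_experiment_admixture
#' @return as [power_experiment_admixture()].
#' @export
power_experiment_partial <- function(s = 0.02, Ne = 10000, stop_freq = 0.8,
                                     n_samples = 50, n_sel = 200,
                                     n_neutral = 1000, lambda = 10,
                                     fpr = 0.001,
                                     artifact = artifact_spec(),
                                     grid_step = 5000, radius = 2e6,
                                     region_bp = 5e6, mu = 1e-8, r = 1e-8,
                                     neutral_mu_factor = 1,
                                     neutral_gens = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- 29
  ## selection model: span generous enough for any accepted sweep
  span_ka <- 500 * lambda * g / 1000
  m_sel <- constant_model(Ne, span_ka, n_samples)
  m_sel$samples$time_ka <- NA # sample at the trigger generation
  onset_ka <- span_ka - 2 * lambda * g / 1000
  sel <- selection_spec(onset_ka, s, branch = "POP")
  grid <- seq(grid_step, region_bp, by = grid_step)
  ## neutral model: fixed duration near the median sweep stopping time
  m_neu <- constant_model(Ne, neutral_gens * lambda * g / 1000, n_samples)
  neu <- .simulate_records(m_neu, NULL, n_neutral, "POP", artifact,
                           region_bp, mu, r, lambda, neutral_mu_factor)
  bg <- background_sfs(do.call(rbind, neu$records))
  tables <- clr_tables(bg)
  neutral_max <- .max_clr(neu$records, bg, tables, grid, radius,
                          alpha_grid_default())
  threshold <- fpr_threshold(neutral_max, fpr)
  selr <- .simulate_records(m_sel, sel, n_sel, "POP", artifact, region_bp,
                            mu, r, lambda, neutral_mu_factor,
                            stop_at_freq = stop_freq)
  sel_max <- .max_clr(selr$records, bg, tables, grid, radius,
                      alpha_grid_default())
  pw <- estimate_power(sel_max, threshold)
  c(pw, list(neutral_max = neutral_max, sel_max = sel_max, bg = bg,
             mean_attempts = mean(selr$attempts),
             mean_final_freq = mean(selr$benef_freq),
             scenario = list(s = s, Ne = Ne, stop_freq = stop_freq,
                             lambda = lambda, fpr = fpr)))
}

#' FDR of the gene-level pipeline on neutral genomes
#'
#' Assembles neutral "genomes" by tiling independent region replicates as
#' chromosomes, runs the full gene-score + two-tier region pipeline on
#' each, counts regions called (false positives) and estimates
#' \eqn{\widehat{FDR} = \bar{FP} / (\bar{FP} + D)} with `D` the assumed
#' true discovery count.
#'
#' @param n_genomes neutral genome replicates (>= 30 recommended).
#' @param n_regions_per_genome 5-Mb regions tiled per genome.
#' @param D assumed true discoveries (default 57).
#' @param genes_per_region synthetic gene annotations per region.
#' @param q_build,q_define two-tier thresholds.
#' @inheritParams power_experiment_admixture
#' @return list `fdr_hat`, `fp_per_genome`, `D`, `mean_fp`.
#' @export
estimate_fdr <- function(n_genomes = 30, n_regions_per_genome = 20, D = 57,
                         genes_per_region = 20, q_build = 0.1,
                         q_define = 0.01, population = "POP",
                         model = constant_model(10000, 29, 50),
                         artifact = artifact_spec(), lambda = 10,
                         grid_step = 5000, radius = 2e6, region_bp = 5e6,
                         mu = 1e-8, r = 1e-8, neutral_mu_factor = 1,
                         seed = NULL) {
  if (D <= 0) stop("D must be > 0")
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(grid_step, region_bp, by = grid_step)
  gene_w <- region_bp / genes_per_region
  genes1 <- data.frame(gene = seq_len(genes_per_region),
                       start = (seq_len(genes_per_region) - 1) * gene_w + 1,
                       end = seq_len(genes_per_region) * gene_w)
  ## shared background from one batch of neutral replicates
  neu <- .simulate_records(model, NULL, max(100, n_regions_per_genome),
                           population, artifact, region_bp, mu, r, lambda,
                           neutral_mu_factor)
  bg <- background_sfs(do.call(rbind, neu$records))
  tables <- clr_tables(bg)
  fp <- integer(n_genomes)
  for (gme in seq_len(n_genomes)) {
    tracks <- list()
    genes <- list()
    for (rg in seq_len(n_regions_per_genome)) {
      rep <- simulate_replicate(model, NULL, region_bp, mu, r, lambda,
                                neutral_mu_factor, new_mutations = FALSE)
      art <- apply_adna_artifacts(rep$populations[[population]],
                                  rep$positions, artifact, rep$panel)
      tr <- suppressWarnings(clr_scan(art$records, bg, grid,
                                      alpha_grid_default(), radius,
                                      tables = tables))
      if (nrow(tr) == 0) next
      ch <- sprintf("chr%d", rg)
      tracks[[rg]] <- cbind(chrom = ch, tr)
      g1 <- genes1
      g1$gene <- sprintf("g%d_%d", rg, genes1$gene)
      g1$chrom <- ch
      genes[[rg]] <- g1
    }
    track <- do.call(rbind, tracks)
    gtab <- do.call(rbind, genes)
    gtab$midpoint <- floor((gtab$start + gtab$end) / 2)
    sc <- gene_scores(track, gtab, population = population)
    reg <- sweep_regions(sc, q_build, q_define)
    fp[gme] <- nrow(reg)
  }
  list(fdr_hat = mean(fp) / (mean(fp) + D), fp_per_genome = fp,
       mean_fp = mean(fp), D = D)
}

#' Run a configured simulation experiment
#'
#' Dispatches on `config$type` (`"power_admixture"`, `"power_partial"`,
#' `"fdr"`), forwarding `config$params`; writes result TSV and metadata
#' JSON when `out_dir` is given.  Identical `(config, seed)` reruns give
#' identical outputs.
#'
#' @param config list with `type` and `params`.
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param dry_run validate the configuration without simulating.
#' @export
run_experiment <- function(config, seed, out_dir = NULL, dry_run = FALSE) {
  types <- c(power_admixture = "power_experiment_admixture",
             power_partial = "power_experiment_partial",
             fdr = "estimate_fdr")
  if (!config$type %in% names(types))
    stop("unknown experiment type: ", config$type)
  fn <- get(types[[config$type]], mode = "function")
  args <- config$params
  bad <- setdiff(names(args), names(formals(fn)))
  if (length(bad)) stop("invalid parameter(s): ", paste(bad, collapse = ", "))
  if (dry_run) return(invisible(TRUE))
  args$seed <- seed
  res <- do.call(fn, args)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- res[vapply(res, function(x)
      is.numeric(x) && length(x) <= 2, TRUE)]
    utils::write.table(
      data.frame(key = names(flat),
                 value = vapply(flat, function(x)
                   paste(signif(x, 8), collapse = ","), "")),
      file.path(out_dir, paste0(config$type, "_results.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_metadata(file.path(out_dir, paste0(config$type, "_meta.json")),
                       seed, config)
  }
  res
}
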