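test_that("replicates are bit-identical under the same seed", {
  m <- constant_model(1000, 10, 20)
  set.seed(61)
  a <- simulate_replicate(m, NULL, region_bp = 5e5, lambda = 10)
  set.seed(61)
  b <- simulate_replicate(m, NULL, region_bp = 5e5, lambda = 10)
  expect_identical(a$populations, b$populations)
  expect_identical(a$positions, b$positions)
})

test_that("rescaling preserves the diffusion-scale compound parameters", {
  m <- west_eurasian_model()
  sel <- selection_spec(44, 0.01)
  r1 <- rescale(m, sel, mu = 1e-8, r = 1e-8, lambda = 1)
  r10 <- rescale(m, sel, mu = 1e-8, r = 1e-8, lambda = 10)
  expect_equal(r1$model$branches$Ne * r1$mu,
               r10$model$branches$Ne * r10$mu, tolerance = 1e-12)
  expect_equal(r1$model$branches$Ne * r1$r,
               r10$model$branches$Ne * r10$r, tolerance = 1e-12)
  expect_equal(r1$model$branches$Ne * r1$selection$s,
               r10$model$branches$Ne * r10$selection$s, tolerance = 1e-12)
  ## identity at lambda = 1
  expect_equal(r1$model$branches, m$branches)
  expect_equal(r1$selection$s, sel$s)
})

test_that("neutral site frequencies are martingales", {
  set.seed(62)
  cm <- constant_model(2000, 10, 100)
  d <- replicate(25, {
    r <- simulate_replicate(cm, NULL, region_bp = 1e6, lambda = 10,
                            new_mutations = FALSE, sample_panel = FALSE)
    mean(colMeans(r$populations$POP)[seq_along(r$init_freq)] - r$init_freq)
  })
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("admixture pulses deliver the configured ancestry fraction", {
  set.seed(63)
  m <- west_eurasian_model()
  m$samples <- m$samples[m$samples$population == "EF", ] # sampled at 7 ka
  f <- replicate(20, {
    r <- simulate_replicate(m, NULL, lambda = 10, new_mutations = FALSE,
                            sample_panel = FALSE,
                            ancestry_marker_branch = "WHG")
    mean(r$populations$EF[, r$marker_col])
  })
  ## EF post-dates only the 50% WHG pulse
  expect_lt(abs(mean(f) - 0.5), 3 * sd(f) / sqrt(length(f)) + 0.02)
})

test_that("neutral equilibrium diversity matches 4 Ne mu", {
  set.seed(64)
  Ne <- 250
  gens <- 10 * Ne
  g <- 29
  m <- constant_model(Ne, gens * g / 1000, 50)
  pis <- replicate(20, {
    r <- simulate_replicate(m, NULL, region_bp = 2e5, mu = 1e-7, r = 1e-7,
                            lambda = 1, neutral_mu_factor = 1,
                            init_min_maf = 1 / (2 * Ne),
                            new_mutations = TRUE, sample_panel = FALSE)
    M <- r$populations$POP
    p <- colMeans(M)
    n <- nrow(M)
    sum(2 * p * (1 - p) * n / (n - 1)) / 2e5
  })
  expect_lt(abs(mean(pis) - 4 * Ne * 1e-7) / (4 * Ne * 1e-7), 0.10)
})

test_that("establishment conditioning matches diffusion theory", {
  set.seed(65)
  Ne <- 500
  m <- constant_model(Ne, 29 * 300 / 1000, 20)
  sel <- selection_spec(29 * 299 / 1000, 0.1, branch = "POP")
  att <- vapply(1:200, function(i) {
    r <- simulate_replicate(m, sel, region_bp = 1e4, lambda = 1,
                            sample_panel = FALSE, condition_min_freq = 0.1)
    r$attempts
  }, 0)
  ## acceptance rate = P(hit frequency 0.1 before loss from one copy)
  p_th <- -expm1(-0.1) / -expm1(-2 * Ne * 0.1 * 0.1)
  p_obs <- length(att) / sum(att)
  se <- sqrt(p_th * (1 - p_th) / sum(att))
  expect_lt(abs(p_obs - p_th), 4 * se)
  ## accepted replicates all satisfy the condition
  r <- simulate_replicate(m, sel, region_bp = 1e4, lambda = 1,
                          sample_panel = FALSE, condition_min_freq = 0.1)
  expect_gte(max(r$trajectories$POP), 0.1)
})

test_that("condition_establishment wraps external generators", {
  set.seed(66)
  gen <- function() list(trajectories = list(p = runif(1)))
  r <- condition_establishment(gen, min_freq = 0.5, max_tries = 1000)
  expect_gte(max(r$trajectories$p), 0.5)
  expect_gte(r$attempts, 1)
  gen0 <- function() list(trajectories = list(p = 0))
  expect_error(condition_establishment(gen0, max_tries = 50), "acceptance")
})

test_that("pseudohaploidisation draws one allele fairly", {
  set.seed(67)
  ## heterozygous diploid site: call is 0 or 1 with empirical frequency 1/2
  H <- rbind(rep(0L, 10000), rep(1L, 10000))  # one individual, het everywhere
  art <- artifact_spec(ascertain = FALSE, beta_a = 1, beta_b = 1,
                       missing_max = 0, target_variants = 10000L)
  res <- apply_adna_artifacts(H, seq_len(10000), art)
  f <- mean(res$calls)
  expect_lt(abs(f - 0.5), 3 * 0.5 / sqrt(10000))
})

test_that("panel ascertainment keeps panel-heterozygous sites only", {
  afr <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L), c(0L, 0L, 0L), c(0L, 0L, 0L))
  eur <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 0L, 0L))
  keep <- ascertain_sites(list(afr = afr, eur = eur))
  ## site 1 monomorphic in all four diploids: removed; sites 2 and 3 kept
  expect_equal(keep, c(FALSE, TRUE, TRUE))
  ## no missingness + target above the site count leaves dimensions intact
  H <- matrix(rbinom(40, 1, 0.5), nrow = 4)
  art <- artifact_spec(ascertain = FALSE, missing_max = 0,
                       missing_rates = rep(0, 5), target_variants = 100L)
  expect_warning(res <- apply_adna_artifacts(H, 1:10, art), "survive")
  expect_equal(dim(res$calls), c(2L, 10L))
  expect_true(!anyNA(res$calls))
})

test_that("ascertained spectra are depleted of singletons", {
  set.seed(68)
  m <- constant_model(1000, 29 * 100 / 1000, 60)
  raw1 <- 0
  asc1 <- 0
  for (i in 1:15) {
    r <- simulate_replicate(m, NULL, region_bp = 2e6, lambda = 10,
                            init_min_maf = 0.001)
    raw <- suppressWarnings(apply_adna_artifacts(
      r$populations$POP, r$positions,
      artifact_spec(ascertain = FALSE, target_variants = 10000L),
      r$panel))$records
    asc <- suppressWarnings(apply_adna_artifacts(
      r$populations$POP, r$positions,
      artifact_spec(target_variants = 10000L), r$panel))$records
    raw <- raw[raw$poly, ]
    asc <- asc[asc$poly, ]
    raw1 <- raw1 + mean(pmin(raw$x, raw$n - raw$x) == 1)
    asc1 <- asc1 + mean(pmin(asc$x, asc$n - asc$x) == 1)
  }
  expect_lt(asc1, raw1)
})

test_that("the bundled sampling design matches the study configuration", {
  sa <- west_eurasian_model()$samples
  expect_equal(sa$n[match(c("AnatolianEF", "WHG", "Steppe", "EF", "LNBA",
                            "ModernEuropeans"), sa$population)],
               c(28L, 45L, 68L, 78L, 192L, 200L))
  expect_equal(sa$time_ka[sa$population == "AnatolianEF"], 8.5)
  expect_equal(sa$time_ka[sa$population == "ModernEuropeans"], 0)
  ## 200 replicates per selection scenario is the default experiment size
  expect_equal(formals(power_experiment_admixture)$n_sel, 200)
})

test_that("neutral background spectra are normalised per population", {
  set.seed(69)
  m <- constant_model(500, 2.9, 15)
  bgs <- suppressWarnings(
    neutral_background(m, n_replicates = 6, region_bp = 1e6, lambda = 10,
                       artifact = artifact_spec(target_variants = 500L),
                       seed = 70))
  expect_named(bgs, "POP")
  expect_s3_class(bgs$POP, "background_sfs")
  expect_equal(sum(bgs$POP$probs), 1, tolerance = 1e-12)
  expect_true(all(bgs$POP$probs >= 0))
})
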