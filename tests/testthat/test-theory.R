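test_that("selection strength follows r ln(2Ne)/alpha and is Ne-robust", {
  expect_equal(selection_strength(1e-5, 1e-8, 1e4), 1e-3 * log(2e4),
               tolerance = 1e-12)
  ## round trip alpha(s) -> s(alpha)
  s <- 0.013
  alpha <- 1e-8 * log(2e4) / s
  expect_equal(selection_strength(alpha, 1e-8, 1e4), s, tolerance = 1e-12)
  ## doubling Ne inflates s only by ln(4Ne)/ln(2Ne)
  ratio <- selection_strength(1e-5, 1e-8, 2e4) /
    selection_strength(1e-5, 1e-8, 1e4)
  expect_equal(ratio, log(4e4) / log(2e4), tolerance = 1e-12)
  expect_lt(ratio, 1.08)
  expect_error(selection_strength(-1, 1e-8), "> 0")
})

test_that("signal persistence is 0.2 Ne generations in years", {
  expect_equal(signal_loss_time(10000, 29), 58000)
  expect_equal(signal_loss_time(2 * 10000, 29), 2 * 58000)  # linear in Ne
  expect_equal(signal_loss_time(10000, 2 * 29), 2 * 58000)  # linear in g
  ## the bundled demography reproduces the ~11 kyr (WHG) vs ~70 kyr (Main
  ## Eurasian) persistence contrast
  br <- west_eurasian_model()$branches
  t_whg <- signal_loss_time(br$Ne[br$name == "WHG"])
  t_main <- signal_loss_time(br$Ne[br$name == "MAIN"])
  expect_equal(t_whg, 11000, tolerance = 0.1)
  expect_equal(t_main, 70000, tolerance = 0.05)
})

test_that("diversity trough reduces to the uniform-rate escape profile", {
  map <- data.frame(chrom = "1", pos = seq(0, 2e6, by = 1e4),
                    rate_cM_Mb = 1.3,
                    map_cM = seq(0, 2e6, by = 1e4) * 1.3e-6)
  s <- 0.02
  Ne <- 1e4
  prof <- diversity_profile(map, 1e6, s, Ne)
  expect_equal(prof$rel_diversity[prof$pos == 1e6], 0)
  ## algebraic equivalence: uniform rate r gives p_e with
  ## alpha = r ln(2Ne)/s
  r <- 1.3e-8
  alpha <- r * log(2 * Ne) / s
  pe <- escape_probability(alpha, abs(prof$pos - 1e6))
  expect_equal(prof$rel_diversity, 1 - (1 - pe)^2, tolerance = 1e-10)
  ## distant positions recover full diversity
  bigmap <- data.frame(chrom = "1", pos = c(0, 1e9), rate_cM_Mb = 1,
                       map_cM = c(0, 1e9 * 1e-6))
  far <- diversity_profile(bigmap, 1000, s, Ne, positions = 1e9)
  expect_equal(far$rel_diversity, 1, tolerance = 1e-6)
  expect_error(diversity_profile(map, 1e6, -0.1, Ne), "s must")
  expect_error(diversity_profile(map, 9e9, s, Ne), "outside")
})

test_that("origin probabilities have the stated limits", {
  expect_equal(suppressWarnings(p_fix_window_denovo(theory_params(T_years = 0))), 0)
  expect_equal(p_fix_window_denovo(theory_params(mu = 0)), 0)
  expect_equal(p_fix_window_sgv(theory_params(mu = 0)), 0)
  ## strong purifying selection wipes out standing rescue
  expect_lt(p_fix_window_sgv(theory_params(s_d = 10)), 1e-4)
  ## rescue-precedence combination limits
  p_only_sgv <- theory_params(T_years = 0)   # no de novo window
  expect_equal(suppressWarnings(sgv_relative_probability(p_only_sgv)), 1)
  p_no_sgv <- theory_params(s_d = 1e6)
  expect_lt(sgv_relative_probability(p_no_sgv), 1e-3)
  expect_true(is.na(sgv_relative_probability(theory_params(mu = 0))))
  ## window shorter than the fixation lag
  expect_warning(v <- p_fix_window_denovo(theory_params(T_years = 500)),
                 "lag")
  expect_equal(v, 0)
})

test_that("SGV relative probability decreases with purifying selection", {
  sd_grid <- c(2e-4, 5e-4, 1e-3, 3e-3, 1e-2, 5e-2)
  vals <- vapply(sd_grid, function(sd)
    sgv_relative_probability(theory_params(s_d = sd)), 0)
  expect_true(all(diff(vals) < 0))
  ## and increases with the mutational target size
  L_grid <- c(100, 300, 1000, 3000)
  vals2 <- vapply(L_grid, function(L)
    p_fix_window_sgv(theory_params(L = L)), 0)
  expect_true(all(diff(vals2) > 0))
})

test_that("hardness probabilities behave across the target-size range", {
  ## single origin forced as Theta -> 0
  expect_equal(hard_sweep_probability(theory_params(L = 1e-9), "denovo"), 1,
               tolerance = 1e-6)
  ## for standing variants hardness counts standing copies (not mutational
  ## origins), so even a single-origin allele can found a soft sweep; the
  ## probability still rises as the target (hence Theta) shrinks
  expect_gt(hard_sweep_probability(theory_params(L = 1), "sgv"),
            hard_sweep_probability(theory_params(L = 3000), "sgv"))
  ## large Theta (>= 10) makes hard de novo sweeps rare
  big <- theory_params(L = 2e5, s_d = 0.001, subtract_lag = FALSE)
  expect_lt(hard_sweep_probability(big, "denovo"), 0.1)
  ## hardness from standing variants rises with prior purifying selection
  h_weak <- hard_sweep_probability(theory_params(s_d = 5e-4), "sgv")
  h_strong <- hard_sweep_probability(theory_params(s_d = 5e-3), "sgv")
  expect_gt(h_strong, h_weak)
  expect_error(hard_sweep_probability(theory_params(), "banana"))
})

test_that("oracle reproduces classical single-copy results", {
  set.seed(51)
  ## neutral fixation probability of one copy is 1/2N
  o <- paleosweep:::.wf_fix_single(400L, 0, 1, 20000L)
  expect_lt(abs(o$p - 1 / 400), 3 * sqrt((1 / 400) * (1 - 1 / 400) / 20000))
  ## establishment probability matches the diffusion formula
  o2 <- paleosweep:::.wf_fix_single(2000L, 0.05, 1, 8000L)
  pi_th <- establishment_prob(0.05, 1000)
  expect_lt(abs(o2$p - pi_th), 3 * o2$se)
  ## same seed gives identical output
  set.seed(99)
  a <- paleosweep:::.wf_fix_single(100L, 0.1, 1, 500L)
  set.seed(99)
  b <- paleosweep:::.wf_fix_single(100L, 0.1, 1, 500L)
  expect_identical(a, b)
})

test_that("closed forms agree with the WF oracle across a parameter grid", {
  set.seed(52)
  grid <- list(
    theory_params(),                                    # reference regime
    theory_params(s_d = 0.01),                          # strong purifying
    theory_params(s_b = 0.05),                          # strong beneficial
    theory_params(L = 5000, s_d = 0.003),               # large target
    theory_params(Ne = 2000, bottleneck_factor = 5,
                  s_b = 0.02, s_d = 0.002, L = 2000)    # small-N regime
  )
  for (p in grid) {
    o <- wf_origin_oracle(p, n_replicates = 3000)
    se_dn <- max(o$se_denovo, 1e-4)
    expect_lt(abs(p_fix_window_denovo(p) - o$p_denovo), 3 * se_dn)
    se_sgv <- max(o$se_sgv, 1e-4)
    expect_lt(abs(p_fix_window_sgv(p) - o$p_sgv), 3 * se_sgv)
    if (o$n_fixed > 100) {
      h <- hard_sweep_probability(p, "sgv")
      expect_lt(abs(h - o$p_hard_sgv), 3 * max(o$se_hard_sgv, 0.01))
    }
  }
})
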