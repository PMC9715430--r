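mk_outliers <- function(mids, chrom = "1", pop = "A") {
  data.frame(gene = paste0(pop, seq_along(mids)), chrom = chrom,
             midpoint = mids, population = pop)
}

test_that("outlier genes collapse by single-linkage midpoint chaining", {
  out <- mk_outliers(c(0.1e6, 0.4e6, 1.6e6))
  cc <- collapse_outlier_genes(out, max_dist = 1e6)
  expect_equal(cc$cluster, c(1L, 1L, 2L))       # gaps 0.3 and 1.2 Mb
  expect_equal(collapse_outlier_genes(mk_outliers(5e6))$cluster, 1L)
  cc2 <- collapse_outlier_genes(out, max_dist = 0.2e6)
  expect_equal(cc2$cluster, 1:3)                 # all singletons
  ## chromosome change always breaks a chain
  out2 <- rbind(mk_outliers(c(1e6, 1.3e6)), mk_outliers(1.4e6, chrom = "2"))
  expect_equal(collapse_outlier_genes(out2)$cluster, c(1L, 1L, 2L))
})

test_that("regions merge across populations by shared genes transitively", {
  cl <- rbind(
    data.frame(gene = c("g1", "g2"), chrom = "1", midpoint = c(1, 2) * 1e6,
               population = "A", cluster = 1L),
    data.frame(gene = c("g2", "g3"), chrom = "1", midpoint = c(2, 3) * 1e6,
               population = "B", cluster = 1L))
  m <- merge_across_populations(cl)
  expect_equal(length(unique(m$region)), 1L)
  expect_setequal(m$gene, c("g1", "g2", "g3"))
  ## disjoint clusters stay separate
  cl2 <- rbind(
    data.frame(gene = "g1", chrom = "1", midpoint = 1e6, population = "A",
               cluster = 1L),
    data.frame(gene = "g9", chrom = "1", midpoint = 9e6, population = "B",
               cluster = 1L))
  expect_equal(length(unique(merge_across_populations(cl2)$region)), 2L)
  ## chain closure: A~B and B~C without A~C still one region
  cl3 <- rbind(
    data.frame(gene = c("a", "b"), chrom = "1", midpoint = c(1, 2) * 1e6,
               population = "A", cluster = 1L),
    data.frame(gene = c("b", "c"), chrom = "1", midpoint = c(2, 3) * 1e6,
               population = "B", cluster = 1L),
    data.frame(gene = c("c", "d"), chrom = "1", midpoint = c(3, 4) * 1e6,
               population = "C", cluster = 1L))
  expect_equal(length(unique(merge_across_populations(cl3)$region)), 1L)
})

mk_scores <- function(q, pop, mids = seq_along(q) * 1e5) {
  data.frame(gene = paste0("g", seq_along(q)), population = pop,
             chrom = "1", midpoint = mids, raw_max = 1,
             win_count = 10L, z = 1, p = q / 2, q = q)
}

test_that("two-tier rule keeps only regions with a defining q < 0.01 gene", {
  sc <- rbind(mk_scores(c(0.05, 0.06, 0.5), "A"),
              mk_scores(c(0.005, 0.09, 0.5), "B"))
  reg <- sweep_regions(sc)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$defining_population, "B")
  expect_true(grepl("g1", reg$genes))
  ## min q = 0.05 only: dropped
  reg2 <- sweep_regions(mk_scores(c(0.05, 0.06), "A"))
  expect_equal(nrow(reg2), 0L)
  expect_equal(nrow(sweep_regions(mk_scores(0.5, "A")[0, ])), 0L)
  ## populations excluded from the defining set cannot define a sweep
  reg3 <- sweep_regions(rbind(mk_scores(c(0.005, 0.5), "weak")),
                        defining_populations = "other")
  expect_equal(nrow(reg3), 0L)
})

test_that("region count is monotone in threshold and collapse distance", {
  set.seed(31)
  q <- runif(60)^3
  sc <- mk_scores(q, "A", mids = sort(sample.int(3e7, 60)))
  n_strict <- nrow(sweep_regions(sc, q_define = 0.005))
  n_loose <- nrow(sweep_regions(sc, q_define = 0.05))
  expect_lte(n_strict, n_loose)
  n_d1 <- nrow(sweep_regions(sc, max_dist = 25e4, q_define = 0.05))
  n_d2 <- nrow(sweep_regions(sc, max_dist = 1e6, q_define = 0.05))
  expect_gte(n_d1, n_d2)
  ## merging is idempotent at the region level
  r1 <- sweep_regions(sc, q_define = 0.05)
  r2 <- sweep_regions(sc[sample(nrow(sc)), ], q_define = 0.05)
  expect_equal(r1$id[order(r1$start)], r2$id[order(r2$start)])
})

test_that("presence matrix applies the q < 0.05 rule per population", {
  sc <- rbind(mk_scores(c(0.001, 0.2), "A"),
              mk_scores(c(0.049, 0.2), "B"),
              mk_scores(c(0.051, 0.2), "C"))
  reg <- sweep_regions(sc)
  M <- population_presence_matrix(reg, sc)
  expect_true(M[1, "A"])
  expect_true(M[1, "B"])    # 0.049 < 0.05, boundary per rule
  expect_false(M[1, "C"])
  ## low-power population excluded: no column
  M2 <- population_presence_matrix(reg, sc, populations = c("A", "B"))
  expect_false("C" %in% colnames(M2))
})

test_that("sweep age classification finds the oldest carrying sample", {
  diag <- data.frame(position = 1:10 * 1000, allele = rep(1L, 10))
  full <- data.frame(position = 1:10 * 1000, call = rep(1L, 10))
  none <- data.frame(position = 1:10 * 1000, call = rep(0L, 10))
  sparse <- data.frame(position = 1:10 * 1000,
                       call = c(1L, rep(NA_integer_, 9)))
  panel <- list(oldest = full, mid = none, youngest = none)
  expect_equal(sweep_age_classify(diag, panel)$class, "oldest")
  ## nobody carries: pooled youngest class
  panel2 <- list(oldest = none, mid = none, youngest = none)
  expect_equal(sweep_age_classify(diag, panel2)$class, "youngest")
  ## 10% coverage cannot support a carrier call
  panel3 <- list(oldest = sparse, mid = none, youngest = full)
  res <- sweep_age_classify(diag, panel3)
  expect_false(res$detail$carries[1])
  expect_equal(res$class, "youngest")
  expect_true(is.na(sweep_age_classify(diag[0, ], panel)$class))
})

test_that("presence-by-group LRT matches the grid-search oracle", {
  y <- c(1, 1, 0, 1, 0, 0, 0, 1)
  g <- rep(c("a", "b"), each = 4)
  res <- presence_group_test(y, g)
  expect_equal(res$lrt, enum_group_lrt(y, g), tolerance = 1e-5)
  expect_equal(res$df, 1L)
  ## identical proportions: LRT ~ 0, P ~ 1
  res0 <- presence_group_test(c(1, 0, 1, 0), rep(c("a", "b"), each = 2))
  expect_lt(res0$lrt, 1e-10)
  expect_gt(res0$p_value, 0.999)
  ## boundary group (all present) has a finite LRT via the boundary MLE
  resb <- presence_group_test(c(1, 1, 1, 0, 0, 1), rep(c("a", "b"), each = 3))
  expect_true(is.finite(resb$lrt))
  expect_equal(resb$lrt, enum_group_lrt(c(1, 1, 1, 0, 0, 1),
                                        rep(c("a", "b"), each = 3)),
               tolerance = 1e-2)
  expect_error(presence_group_test(c(1, 0), c("a", "a")), "2 groups")
})

test_that("selection peak takes the max CLR across tracks, ties leftward", {
  reg <- data.frame(chrom = "1", start = 1e6, end = 2e6)
  trA <- data.frame(chrom = "1", position = c(1.2e6, 1.5e6),
                    clr = c(5, 8), alpha_hat = c(1e-5, 2e-5))
  trB <- data.frame(chrom = "1", position = c(1.4e6), clr = 12,
                    alpha_hat = 3e-5)
  pk <- estimate_selection_peak(reg, list(A = trA, B = trB))
  expect_equal(pk$population, "B")
  expect_equal(pk$alpha_hat, 3e-5)
  ## tie at two positions resolves to the smaller coordinate
  trC <- data.frame(chrom = "1", position = c(1.3e6, 1.6e6), clr = c(9, 9),
                    alpha_hat = c(1e-5, 2e-5))
  pk2 <- estimate_selection_peak(reg, list(C = trC))
  expect_equal(pk2$position, 1.3e6)
})

test_that("BED export converts to 0-based half-open intervals", {
  reg <- data.frame(chrom = "1", start = 1001, end = 2000, id = "1:0.0-0.0")
  f <- file.path(tempdir(), "reg.bed")
  write_regions_bed(reg, f)
  bed <- utils::read.table(f)
  expect_equal(bed$V2, 1000L)
  expect_equal(bed$V3, 2000L)
})
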