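test_that("EIGENSTRAT round trip reproduces calls bit-exactly", {
  gm <- toy_gm()
  pre <- file.path(tempdir(), "toy")
  write_eigenstrat(gm, pre)
  gm2 <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                         paste0(pre, ".ind"))
  expect_identical(gm2$calls, unname(gm$calls))
  expect_equal(gm2$ploidy, 1L)
  expect_equal(gm2$sites$pos, gm$sites$pos)
})

test_that("EIGENSTRAT reader maps 9 to missing and validates shape", {
  d <- tempdir()
  writeLines(c("01", "91", "00"), file.path(d, "a.geno"))
  writeLines(c("s1\t1\t0\t100\tA\tT", "s2\t1\t0\t200\tA\tT",
               "s3\t1\t0\t300\tA\tT"), file.path(d, "a.snp"))
  writeLines(c("i1\tU\tpop", "i2\tU\tpop"), file.path(d, "a.ind"))
  gm <- read_eigenstrat(file.path(d, "a.geno"), file.path(d, "a.snp"),
                        file.path(d, "a.ind"))
  expect_identical(gm$calls[, 2], c(NA_integer_, 1L))
  expect_equal(sum(is.na(gm$calls)), 1L)
  ## non-monotone positions rejected
  writeLines(c("s1\t1\t0\t300\tA\tT", "s2\t1\t0\t200\tA\tT",
               "s3\t1\t0\t400\tA\tT"), file.path(d, "a.snp"))
  expect_error(read_eigenstrat(file.path(d, "a.geno"), file.path(d, "a.snp"),
                               file.path(d, "a.ind")),
               "strictly increasing")
  ## row-count mismatch names the offending line
  writeLines(c("01", "911", "00"), file.path(d, "b.geno"))
  writeLines(c("s1\t1\t0\t100\tA\tT", "s2\t1\t0\t200\tA\tT",
               "s3\t1\t0\t300\tA\tT"), file.path(d, "a.snp"))
  expect_error(read_eigenstrat(file.path(d, "b.geno"), file.path(d, "a.snp"),
                               file.path(d, "a.ind")), "line 2")
})

test_that("VCF reader handles pseudohaploid encodings and multi-allelics", {
  skip_if_not_installed("vcfR")
  vcf <- file.path(tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/0\t1\t./.",
    "1\t200\t.\tG\tC,T\t.\t.\t.\tGT\t0/0\t0/0\t1/1",
    "1\t300\t.\tA\tG\t.\t.\t.\tGT\t1/1\t0\t1"), vcf)
  expect_warning(gm <- read_vcf_pseudohaploid(vcf), "multi-allelic")
  expect_equal(attr(gm, "skipped"), 1L)
  expect_equal(nrow(gm$sites), 2L)
  expect_identical(unname(gm$calls[, 1]), c(0L, 1L, NA_integer_))
  expect_identical(unname(gm$calls[, 2]), c(1L, 0L, 1L))
  ## heterozygous genotype is an error in pseudohaploid mode
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1"), vcf)
  expect_error(read_vcf_pseudohaploid(vcf), "heterozygous")
  ## equivalence with the EIGENSTRAT representation of the same content
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\t.\tA\tT\t.\t.\t.\tGT\t0\t1",
    "1\t200\t.\tA\tT\t.\t.\t.\tGT\t./.\t1",
    "1\t300\t.\tA\tT\t.\t.\t.\tGT\t0\t0"), vcf)
  gv <- read_vcf_pseudohaploid(vcf)
  ge <- toy_gm()
  expect_identical(unname(gv$calls), unname(ge$calls))
})

test_that("site_allele_counts conserves calls and drops empty sites", {
  gm <- toy_gm()
  rec <- site_allele_counts(gm)
  expect_equal(rec$x, c(1L, 1L, 0L))
  expect_equal(rec$n, c(2L, 1L, 2L))
  expect_false(rec$poly[3]) # monomorphic-in-sample retained but flagged
  ## conservation: x + ref + missing = sample count, per site
  set.seed(1)
  calls <- matrix(sample(c(0L, 1L, NA), 200, replace = TRUE), nrow = 10)
  sites <- data.frame(chrom = "1", pos = seq_len(20) * 10L, ref = "A",
                      alt = "T")
  g2 <- genotype_matrix(paste0("s", 1:10), sites, calls)
  r2 <- site_allele_counts(g2)
  nmiss <- colSums(is.na(calls))[match(r2$position, sites$pos)]
  expect_true(all(r2$x + (r2$n - r2$x) + nmiss == 10))
  ## all-missing site omitted
  calls[, 3] <- NA_integer_
  r3 <- site_allele_counts(genotype_matrix(paste0("s", 1:10), sites, calls))
  expect_false(30L %in% r3$position)
  expect_error(site_allele_counts(gm, "nope"), "unknown sample")
})

test_that("background projection equals exhaustive subset enumeration", {
  ## the worked example: x = 2 of n = 4 projected to n_ref = 2
  en <- enum_projection(2, 4, 2)
  expect_equal(en[2], 2 / 3, tolerance = 1e-12)
  rec <- data.frame(chrom = "1", position = 1000, x = 2L, n = 4L,
                    folded = 0L)
  bg <- background_sfs(rec, n_ref = 2)
  expect_equal(bg$probs, en[2] / sum(en[2]), tolerance = 1e-12)
  ## random small cases, exact comparison against enumeration
  set.seed(42)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    x <- sample(seq_len(n - 1), 1)
    n_ref <- sample(2:(n - 1), 1)
    en <- enum_projection(x, n, n_ref)
    rec <- data.frame(chrom = "1", position = 1000, x = x, n = n,
                      folded = 0L)
    bg <- background_sfs(rec, n_ref = n_ref)
    expect_equal(bg$probs, en[2:n_ref] / sum(en[2:n_ref]),
                 tolerance = 1e-12)
  }
})

test_that("background spectrum normalises, pools sites and errors when empty", {
  rec <- data.frame(chrom = "1", position = c(1, 2, 3) * 100,
                    x = c(1L, 1L, 1L), n = c(10L, 10L, 10L), folded = 0L)
  bg <- background_sfs(rec, n_ref = 10)
  expect_equal(sum(bg$probs), 1, tolerance = 1e-12)
  expect_equal(bg$probs[1], 1) # all singletons at n = n_ref
  mono <- data.frame(chrom = "1", position = 100, x = 0L, n = 10L,
                     folded = 0L)
  expect_error(background_sfs(mono), "no polymorphic")
})

test_that("effective sample size follows kn(1 - M) with inclusive threshold", {
  expect_equal(effective_sample_size(28, 1, 0.25)$n_eff, 21)
  expect_true(effective_sample_size(28, 1, 0.25)$pass)
  r <- effective_sample_size(5, 2, 0.5)
  expect_equal(r$n_eff, 5)
  expect_false(r$pass)
  expect_true(effective_sample_size(10, 1, 0)$pass) # boundary inclusive
  expect_error(effective_sample_size(10, 1, 1.5), "M must be")
})

test_that("SweepFinder-format files round trip and validate ordering", {
  rec <- data.frame(position = c(1000, 2000), x = c(3L, 5L), n = c(10L, 9L),
                    folded = c(1L, 1L))
  f <- file.path(tempdir(), "sf.txt")
  write_sf_input(rec, f)
  expect_length(readLines(f), 3L) # header + 2 rows
  back <- read_sf_input(f)
  expect_equal(back[, 1:4], rec)
  expect_error(write_sf_input(rec[2:1, ], f), "ascending")
  expect_error(write_sf_input(rec[c(1, 1), ], f), "duplicate")
})

test_that("recombination map loads and interpolates genetic distance", {
  f <- file.path(tempdir(), "map.txt")
  writeLines(c("chrom\tpos\trate\tmap",
               "1\t0\t1.0\t0", "1\t1000000\t1.0\t1", "1\t2000000\t3.0\t3"),
             f)
  m <- read_recombination_map(f)
  expect_equal(genetic_position(m, 500000), 0.005) # 0.5 cM in Morgans
  expect_equal(genetic_position(m, 1500000), 0.02)
  writeLines(c("chrom\tpos\trate\tmap", "1\t0\t1.0\t2", "1\t1000\t1.0\t1"),
             f)
  expect_error(read_recombination_map(f), "decreases")
})

test_that("gene annotations load with computed midpoints", {
  f <- file.path(tempdir(), "genes.tsv")
  writeLines(c("gene\tchrom\tstart\tend", "G1\t1\t100\t301",
               "G2\t2\t1000\t5000"), f)
  g <- read_gene_annotation(f)
  expect_equal(g$midpoint, c(200L, 3000L))
  writeLines(c("gene\tchrom\tstart\tend", "G1\t1\t500\t100"), f)
  expect_error(read_gene_annotation(f), "start > end")
})

test_that("run metadata sidecar records seed and configuration", {
  f <- file.path(tempdir(), "meta.json")
  write_run_metadata(f, seed = 42L, config = list(grid_step = 1000))
  meta <- jsonlite::read_json(f)
  expect_equal(meta$seed, 42L)
  expect_equal(meta$config$grid_step, 1000)
  expect_equal(meta$package, "paleosweep")
})
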