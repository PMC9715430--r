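## Data model and I/O: pseudohaploid genotype matrices, per-population
## allele-frequency records, the genome-wide background SFS, effective sample
## sizes, and the standard text formats used around them.

MISSING <- NA_integer_

#' Pseudohaploid genotype matrix
#'
#' Container for per-sample calls at ordered variant sites.  Calls are coded
#' 0 (reference allele), 1 (alternate allele) or `NA` (missing); one call per
#' sample per site, as produced by pseudohaploidisation of ancient-DNA read
#' data (a single read sampled per site).  `ploidy` records whether each
#' call summarises one (`1`) or two (`2`) underlying chromosomes, which only
#' enters the effective sample size \eqn{n_{eff} = k n (1 - M)}.
#'
#' @param samples character vector of sample identifiers.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; positions must be strictly increasing within a chromosome.
#' @param calls integer matrix (samples x sites) with values in
#'   `{0, 1, NA}`.
#' @param ploidy 1 for pseudohaploid calls, 2 for diploid-derived calls.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, sites, calls, ploidy = 1L) {
  stopifnot(is.character(samples), is.data.frame(sites))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples))
    stop("calls must have one row per sample")
  if (ncol(calls) != nrow(sites))
    stop("calls must have one column per site")
  if (!all(calls %in% c(0L, 1L, NA_integer_)))
    stop("calls must be 0, 1 or NA")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  structure(list(samples = samples, sites = sites, calls = calls,
                 ploidy = as.integer(ploidy)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (ploidy %d), %.1f%% missing\n",
              length(x$samples), nrow(x$sites), x$ploidy,
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read an EIGENSTRAT genotype triplet
#'
#' Reads `geno`/`snp`/`ind` files.  Genotype characters are interpreted as
#' alternate-allele dosage: pseudohaploid files use `{0, 1, 9}` (ploidy 1);
#' files containing a `2` are taken as diploid homozygous-coded pseudohaploid
#' data (`0` -> 0, `2` -> 1, ploidy 2) in which a `1` (heterozygote) is an
#' error.  `9` is missing everywhere.
#'
#' @param geno_path,snp_path,ind_path file paths.
#' @return A [genotype_matrix()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path) {
  ind <- utils::read.table(ind_path, header = FALSE,
                           stringsAsFactors = FALSE)
  samples <- as.character(ind[[1]])
  snp <- utils::read.table(snp_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(snp) < 4) stop("snp file needs >= 4 columns")
  ## EIGENSTRAT snp columns: id, chrom, genetic pos, physical pos[, ref, alt]
  sites <- data.frame(chrom = as.character(snp[[2]]),
                      pos = as.integer(snp[[4]]),
                      ref = if (ncol(snp) >= 6) as.character(snp[[5]]) else "A",
                      alt = if (ncol(snp) >= 6) as.character(snp[[6]]) else "T",
                      stringsAsFactors = FALSE)
  lines <- readLines(geno_path)
  lines <- gsub("[[:space:]]", "", lines)
  if (length(lines) != nrow(sites))
    stop(sprintf("geno file has %d lines but snp file %d sites",
                 length(lines), nrow(sites)))
  nbad <- which(nchar(lines) != length(samples))
  if (length(nbad))
    stop(sprintf("geno line %d has %d genotypes for %d samples", nbad[1],
                 nchar(lines[nbad[1]]), length(samples)))
  g <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
              nrow = length(samples))
  diploid <- any(g == "2")
  calls <- matrix(NA_integer_, length(samples), nrow(sites))
  calls[g == "0"] <- 0L
  if (diploid) {
    calls[g == "2"] <- 1L
    if (any(g == "1"))
      stop("heterozygous genotype in diploid-coded pseudohaploid file")
  } else {
    calls[g == "1"] <- 1L
  }
  genotype_matrix(samples, sites, calls, ploidy = if (diploid) 2L else 1L)
}

#' Write an EIGENSTRAT genotype triplet
#'
#' Inverse of [read_eigenstrat()]; round trips calls bit-exactly.
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix; writes `<prefix>.geno`, `.snp`, `.ind`.
#' @export
write_eigenstrat <- function(gm, prefix) {
  code <- gm$calls
  chr <- matrix("9", nrow(code), ncol(code))
  chr[code == 0L & !is.na(code)] <- "0"
  chr[code == 1L & !is.na(code)] <- if (gm$ploidy == 2L) "2" else "1"
  writeLines(apply(chr, 2, paste0, collapse = ""),
             paste0(prefix, ".geno"))
  snp <- data.frame(id = paste0("snp", seq_len(nrow(gm$sites))),
                    chrom = gm$sites$chrom, gpos = 0,
                    pos = gm$sites$pos, ref = gm$sites$ref,
                    alt = gm$sites$alt)
  utils::write.table(snp, paste0(prefix, ".snp"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(data.frame(gm$samples, "U", "pop1"),
                     paste0(prefix, ".ind"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read pseudohaploid genotypes from a VCF
#'
#' Accepts haploid (`0`, `1`) and diploid-homozygous (`0/0`, `1/1`)
#' encodings; `./.` and `.` are missing.  A heterozygous genotype is an
#' error in pseudohaploid data; multi-allelic records are skipped with a
#' warning and counted in the `skipped` attribute.
#'
#' @param vcf_path path to a VCF file (uncompressed or gzipped).
#' @param sample_subset optional character vector of samples to keep.
#' @return A [genotype_matrix()] with a `skipped` attribute.
#' @export
read_vcf_pseudohaploid <- function(vcf_path, sample_subset = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  nskip <- sum(multi)
  if (nskip > 0)
    warning(sprintf("skipped %d multi-allelic record(s)", nskip))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, colnames(gt))
    if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
  }
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt))
  calls[t(gt) %in% c("0", "0/0")] <- 0L
  calls[t(gt) %in% c("1", "1/1")] <- 1L
  het <- t(gt) %in% c("0/1", "1/0")
  if (any(het))
    stop("heterozygous genotype found in pseudohaploid mode")
  sites <- data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = as.character(fix[, "REF"]),
                      alt = as.character(fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  out <- genotype_matrix(colnames(gt), sites, calls, ploidy = 1L)
  attr(out, "skipped") <- nskip
  out
}

#' Per-site allele counts for a population
#'
#' For each site, `x` is the number of alternate (derived) calls among
#' non-missing calls and `n` the number of non-missing calls; sites with
#' `n = 0` are omitted.  Sites monomorphic within the population are
#' retained and flagged (`poly = FALSE`); the sweep scan uses polymorphic
#' sites only.
#'
#' @param gm a [genotype_matrix()].
#' @param population_samples character vector of sample ids.
#' @param folded 1 if the allele labels are reference-polarised without an
#'   ancestral call (default), 0 if the reference allele is ancestral.
#' @return data.frame with columns `chrom`, `position`, `x`, `n`, `folded`,
#'   `poly`.
#' @export
site_allele_counts <- function(gm, population_samples = gm$samples,
                               folded = 1L) {
  idx <- match(population_samples, gm$samples)
  if (anyNA(idx))
    stop("unknown sample id: ",
         paste(population_samples[is.na(idx)], collapse = ", "))
  sub <- gm$calls[idx, , drop = FALSE]
  n <- colSums(!is.na(sub))
  x <- colSums(sub, na.rm = TRUE)
  keep <- n > 0
  data.frame(chrom = gm$sites$chrom[keep], position = gm$sites$pos[keep],
             x = as.integer(x[keep]), n = as.integer(n[keep]),
             folded = as.integer(folded),
             poly = x[keep] > 0 & x[keep] < n[keep])
}

#' Genome-wide background site frequency spectrum
#'
#' Builds the neutral null spectrum used by the composite likelihood ratio:
#' every site with `n >= n_ref` non-missing calls contributes its exact
#' hypergeometric projection to sample size `n_ref`; the spectrum is
#' restricted to polymorphic classes `1..n_ref-1` and renormalised.  With
#' folded records the projected spectrum is symmetrised.  By default `n_ref`
#' is the 5th percentile of the per-site sample sizes, so that at least 95%
#' of sites can be projected down; sites below `n_ref` are dropped from the
#' background (the scan still evaluates them at their own `n` provided
#' `n >= min_n`).
#'
#' @param records data.frame as from [site_allele_counts()].
#' @param n_ref reference sample size (default: 5th percentile of `n`).
#' @param min_n smallest per-site `n` the downstream scan will use.
#' @return object of class `background_sfs` with fields `n_ref`, `probs`
#'   (classes `1..n_ref-1`), `folded`, `min_n`, `n_sites`.
#' @export
background_sfs <- function(records, n_ref = NULL, min_n = 6L) {
  rec <- records[records$x > 0 & records$x < records$n, , drop = FALSE]
  if (nrow(rec) == 0) stop("no polymorphic sites: empty spectrum")
  if (is.null(n_ref))
    n_ref <- max(2L, as.integer(stats::quantile(rec$n, 0.05, type = 1)))
  if (n_ref < 2) stop("n_ref must be >= 2")
  use <- rec[rec$n >= n_ref, , drop = FALSE]
  if (nrow(use) == 0) stop("no usable sites at n_ref = ", n_ref)
  probs <- numeric(n_ref + 1)
  combos <- stats::aggregate(list(w = rep(1, nrow(use))),
                             by = list(x = use$x, n = use$n), FUN = sum)
  for (i in seq_len(nrow(combos))) {
    k <- 0:n_ref
    probs <- probs + combos$w[i] *
      stats::dhyper(k, combos$x[i], combos$n[i] - combos$x[i], n_ref)
  }
  p <- probs[2:n_ref]  # classes 1..n_ref-1
  folded <- all(records$folded == 1L)
  if (folded) p <- (p + rev(p)) / 2
  p <- p / sum(p)
  structure(list(n_ref = as.integer(n_ref), probs = p, folded = folded,
                 min_n = as.integer(min_n), n_sites = nrow(use)),
            class = "background_sfs")
}

#' @export
print.background_sfs <- function(x, ...) {
  cat(sprintf("background_sfs: n_ref = %d (%s), %d sites\n", x$n_ref,
              if (x$folded) "folded" else "unfolded", x$n_sites))
  invisible(x)
}

#' Effective sample size of a pseudohaploid population
#'
#' \eqn{n_{eff} = k n (1 - M)} where `k` is the ploidy of the calls, `n` the
#' number of samples and `M` the mean fraction of missing calls at
#' informative SNPs.  Populations with `n_eff < 10` lack power to detect
#' sweeps and are excluded from sweep determination.
#'
#' @param n number of samples.
#' @param k ploidy (1 or 2).
#' @param M mean missing fraction in `[0, 1]`.
#' @param threshold minimum effective size regarded as powered (default 10,
#'   boundary inclusive).
#' @return list with `n_eff` and logical `pass`.
#' @export
effective_sample_size <- function(n, k = 1, M = 0, threshold = 10) {
  if (any(M < 0 | M > 1)) stop("M must be in [0, 1]")
  if (any(n < 0)) stop("n must be >= 0")
  if (!all(k %in% c(1, 2))) stop("k must be 1 or 2")
  n_eff <- k * n * (1 - M)
  list(n_eff = n_eff, pass = n_eff >= threshold)
}

#' Write allele-frequency records in SweepFinder input format
#'
#' Tab-separated with header `position x n folded`, positions ascending.
#' @param records data.frame with `position`, `x`, `n`, `folded`.
#' @param path output path.
#' @export
write_sf_input <- function(records, path) {
  if (nrow(records) == 0) stop("no records to write")
  if (anyDuplicated(records$position))
    stop("duplicate positions in records")
  if (is.unsorted(records$position, strictly = TRUE))
    stop("positions must be strictly ascending")
  utils::write.table(records[, c("position", "x", "n", "folded")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SweepFinder-format allele-frequency file
#' @param path input path.
#' @return data.frame with `position`, `x`, `n`, `folded`, `poly`.
#' @export
read_sf_input <- function(path) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("position", "x", "n", "folded") %in% names(rec)))
  rec$poly <- rec$x > 0 & rec$x < rec$n
  rec
}

#' Read a HapMap-format recombination map
#'
#' Text table with columns chromosome, position (bp), rate (cM/Mb) and
#' cumulative map (cM).
#' @param path input path.
#' @return data.frame `chrom`, `pos`, `rate_cM_Mb`, `map_cM`, validated.
#' @export
read_recombination_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(m)[1:4] <- c("chrom", "pos", "rate_cM_Mb", "map_cM")
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (any(diff(sub$map_cM) < 0))
      stop("cumulative map decreases on chromosome ", ch)
  }
  if (any(m$rate_cM_Mb < 0)) stop("negative recombination rate")
  m
}

#' Genetic distance between positions via a recombination map
#'
#' Linear interpolation of the cumulative map.
#' @param map data.frame from [read_recombination_map()] (one chromosome).
#' @param pos positions (bp).
#' @return cumulative genetic position in Morgans.
#' @export
genetic_position <- function(map, pos) {
  stats::approx(map$pos, map$map_cM, xout = pos, rule = 2)$y / 100
}

#' Read a gene annotation table
#'
#' Tab-separated: gene id, chromosome, start, end (1-based inclusive).
#' @param path input path.
#' @return data.frame with `gene`, `chrom`, `start`, `end`, `midpoint`.
#' @export
read_gene_annotation <- function(path) {
  g <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(g)[1:4] <- c("gene", "chrom", "start", "end")
  if (any(g$start > g$end)) stop("gene start > end")
  g$midpoint <- floor((g$start + g$end) / 2)
  g
}

#' Write a JSON run-metadata sidecar
#' @param path output path (`.json`).
#' @param seed integer seed used.
#' @param config named list of run configuration.
#' @export
write_run_metadata <- function(path, seed, config = list()) {
  meta <- list(package = "paleosweep",
               version = as.character(utils::packageVersion("paleosweep")),
               seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
               config = config)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
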