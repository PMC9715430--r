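## Per-SNP Weir-Cockerham F_st against an outgroup, chi-square-fit outlier
## detection on putatively neutral SNPs, and region-level elevation tests.

#' Haploid two-population Weir-Cockerham F_st
#'
#' ANOVA form for haploid allele draws (pseudohaploid calls are haploid
#' samples, so no heterozygosity term):
#' \eqn{\theta = (MSA - MSW) / (MSA + (n_c - 1) MSW)} with
#' \eqn{MSA = \sum_i n_i (p_i - \bar p)^2 / (r - 1)},
#' \eqn{MSW = \sum_i n_i p_i (1 - p_i) / \sum_i (n_i - 1)} and the usual
#' sample-size correction
#' \eqn{n_c = (\sum n_i - \sum n_i^2 / \sum n_i) / (r - 1)}.
#' Vectorised over sites; undefined (0/0) sites return `NA`.
#'
#' @param p1,p2 allele frequencies in populations 1 and 2.
#' @param n1,n2 haploid sample sizes (>= 2).
#' @return numeric F_st estimates (can be negative).
#' @export
wc_fst <- function(p1, n1, p2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("sample sizes must be >= 2")
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msa <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 - 1 + n2 - 1)
  denom <- msa + (nc - 1) * msw
  ifelse(denom == 0, NA_real_, (msa - msw) / denom)
}

#' F_st records for two populations from a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param pop1_samples,pop2_samples sample id vectors.
#' @return data.frame `chrom`, `position`, `fst`, `he` (pooled expected
#'   heterozygosity), with sites having n < 2 in either population dropped.
#' @export
fst_records <- function(gm, pop1_samples, pop2_samples) {
  a1 <- site_allele_counts(gm, pop1_samples)
  a2 <- site_allele_counts(gm, pop2_samples)
  key1 <- paste(a1$chrom, a1$position)
  key2 <- paste(a2$chrom, a2$position)
  common <- intersect(key1, key2)
  a1 <- a1[match(common, key1), ]
  a2 <- a2[match(common, key2), ]
  keep <- a1$n >= 2 & a2$n >= 2
  a1 <- a1[keep, ]
  a2 <- a2[keep, ]
  p1 <- a1$x / a1$n
  p2 <- a2$x / a2$n
  pbar <- (a1$x + a2$x) / (a1$n + a2$n)
  data.frame(chrom = a1$chrom, position = a1$position,
             fst = wc_fst(p1, a1$n, p2, a2$n),
             he = pbar * (1 - pbar))
}

#' Chi-square outlier fit for F_st records
#'
#' OutFLANK-style neutral-distribution inference: after removing SNPs with
#' expected heterozygosity below `he_min`, a scaled chi-square
#' (\eqn{F_{st} \sim (\bar F / df) \chi^2_{df}} with unknown df and mean)
#' is fitted by maximum likelihood to the central `1 - 2 trim` mass of the
#' positive F_st values (likelihood renormalised by the mass between the
#' empirical trim bounds).  Right-tail P-values and Storey q-values are
#' attached per SNP.
#'
#' @param records data.frame from [fst_records()].
#' @param trim fraction trimmed from each tail for the fit (default 0.05).
#' @param he_min expected-heterozygosity filter (default 0.1).
#' @return list with `df_hat`, `mean_hat`, and `records` (input plus
#'   `p_outlier`, `q_outlier`; NA where `he < he_min` or `fst` undefined).
#' @export
outlier_fit <- function(records, trim = 0.05, he_min = 0.1) {
  ok <- !is.na(records$fst) & records$he >= he_min
  x <- records$fst[ok & records$fst > 0]
  if (length(x) < 1000)
    stop("need >= 1000 positive F_st values after the He filter")
  qs <- stats::quantile(x, c(trim, 1 - trim), type = 7)
  xi <- x[x >= qs[1] & x <= qs[2]]
  nll <- function(par) {
    df <- exp(par[1])
    mu <- exp(par[2])
    sc <- df / mu
    mass <- stats::pchisq(qs[2] * sc, df) - stats::pchisq(qs[1] * sc, df)
    if (!is.finite(mass) || mass <= 0) return(1e10)
    -sum(stats::dchisq(xi * sc, df, log = TRUE) + log(sc)) +
      length(xi) * log(mass)
  }
  fit <- stats::optim(c(log(2), log(mean(xi))), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    stop("chi-square fit did not converge (code ", fit$convergence, ")")
  df_hat <- exp(fit$par[1])
  mean_hat <- exp(fit$par[2])
  p <- rep(NA_real_, nrow(records))
  p[ok] <- stats::pchisq(records$fst[ok] * df_hat / mean_hat, df_hat,
                         lower.tail = FALSE)
  q <- rep(NA_real_, nrow(records))
  q[ok] <- storey_qvalues(p[ok])
  records$p_outlier <- p
  records$q_outlier <- q
  list(df_hat = df_hat, mean_hat = mean_hat, records = records,
       n_fit = length(xi))
}

#' One-sided rank-sum test for elevated region F_st
#'
#' Wilcoxon rank-sum (region greater than background), normal approximation
#' with tie correction and continuity correction.  Fully tied input yields
#' P = 0.5; fewer than `min_snps` region values yields `NA`.
#'
#' @param region_fst F_st values of SNPs in the region.
#' @param background_fst background F_st values.
#' @param min_snps minimum region SNPs (default 5).
#' @return one-sided P-value.
#' @export
region_elevation_test <- function(region_fst, background_fst, min_snps = 5) {
  x <- region_fst[!is.na(region_fst)]
  y <- background_fst[!is.na(background_fst)]
  if (length(x) < min_snps) return(NA_real_)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  v <- n1 * n2 / 12 * ((n1 + n2 + 1) - tiecorr)
  if (v <= 0) return(0.5)
  z <- (W - mu - 0.5) / sqrt(v)
  stats::pnorm(z, lower.tail = FALSE)
}
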