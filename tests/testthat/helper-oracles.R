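## Independent brute-force oracles used across test files.

## exhaustive enumeration of the sweep-distorted SFS: every escape pattern,
## every per-lineage allele draw and both hitchhiker alleles, summed exactly
enum_sweep_sfs <- function(bg_probs, n_ref, n, p_e) {
  probs <- numeric(n + 1)
  for (j in seq_len(n_ref - 1)) {
    f <- j / n_ref
    w <- bg_probs[j]
    if (w == 0) next
    for (esc_mask in 0:(2^n - 1)) {
      esc <- as.integer(intToBits(esc_mask))[1:n]
      pe_w <- prod(ifelse(esc == 1, p_e, 1 - p_e))
      if (pe_w == 0) next
      e <- sum(esc)
      for (hh in 0:1) {
        hw <- if (hh == 1) f else 1 - f
        if (e == 0) {
          k <- hh * n
          probs[k + 1] <- probs[k + 1] + w * pe_w * hw
        } else {
          for (am in 0:(2^e - 1)) {
            al <- as.integer(intToBits(am))[1:e]
            aw <- prod(ifelse(al == 1, f, 1 - f))
            k <- sum(al) + hh * (n - e)
            probs[k + 1] <- probs[k + 1] + w * pe_w * hw * aw
          }
        }
      }
    }
  }
  probs
}

## exhaustive subset-enumeration projection of one site (x derived of n) to
## a sample of n_ref calls
enum_projection <- function(x, n, n_ref) {
  calls <- c(rep(1, x), rep(0, n - x))
  sub <- utils::combn(n, n_ref)
  counts <- apply(sub, 2, function(idx) sum(calls[idx]))
  tabulate(counts + 1, nbins = n_ref + 1) / ncol(sub)
}

## brute-force Storey q-values: minimise pi0*m*t/#{p <= t} over observed
## thresholds t >= p_i
enum_storey <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  vapply(p, function(pi) {
    ts <- sort(unique(p[p >= pi - 1e-15]))
    min(1, min(vapply(ts, function(t) pi0 * m * t / sum(p <= t), 0)))
  }, 0)
}

## grid-search maximum Bernoulli log-likelihood over group probabilities
enum_group_lrt <- function(y, g, step = 1e-4) {
  ll <- function(y, p) sum(dbinom(y, 1, p, log = TRUE))
  grid <- seq(step, 1 - step, by = step)
  l0 <- max(vapply(grid, function(p) ll(y, p), 0))
  l1 <- sum(vapply(split(y, g), function(yy)
    max(vapply(grid, function(p) ll(yy, p), 0)), 0))
  2 * (l1 - l0)
}

## tiny genotype-matrix fixture
toy_gm <- function() {
  sites <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                      ref = "A", alt = "T")
  calls <- rbind(s1 = c(0L, NA, 0L), s2 = c(1L, 1L, 0L))
  genotype_matrix(c("s1", "s2"), sites, calls)
}
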