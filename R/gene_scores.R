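## Gene-level sweep evidence: maximum log-transformed CLR per gene window,
## length standardisation, upper-tail P-values and Storey q-values.

#' Assign raw sweep scores to genes
#'
#' Each gene's score is the maximum of `ln(1 + CLR)` over scan-grid
#' positions within the gene extended by `flank` bp on either side (to
#' capture cis-regulatory regions).  Genes overlapping no grid position are
#' dropped and counted.
#'
#' @param track data.frame from [clr_genome_scan()] (`chrom`, `position`,
#'   `clr`).
#' @param genes data.frame from [read_gene_annotation()].
#' @param flank extension in bp on each side (default 50 kb).
#' @return data.frame `gene`, `chrom`, `midpoint`, `raw_max`, `win_count`;
#'   attribute `dropped` counts geneless-of-grid entries.
#' @export
gene_score_assign <- function(track, genes, flank = 50e3) {
  score <- log1p(track$clr)
  raw <- numeric(nrow(genes))
  wc <- integer(nrow(genes))
  ord <- order(track$chrom, track$position)
  track <- track[ord, ]
  score <- score[ord]
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0) {
      wc[gi] <- 0L
      next
    }
    pos <- track$position[ti]
    sc <- score[ti]
    lo <- findInterval(genes$start[gi] - flank - 1, pos) + 1
    hi <- findInterval(genes$end[gi] + flank, pos)
    for (j in seq_along(gi)) {
      if (hi[j] >= lo[j]) {
        rng <- lo[j]:hi[j]
        raw[gi[j]] <- max(sc[rng])
        wc[gi[j]] <- length(rng)
      }
    }
  }
  keep <- wc > 0
  out <- data.frame(gene = genes$gene[keep], chrom = genes$chrom[keep],
                    midpoint = genes$midpoint[keep], raw_max = raw[keep],
                    win_count = wc[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Length-standardise gene scores
#'
#' Nonparametric standardisation: genes are grouped into `n_bins`
#' equal-occupancy bins by window count (the length proxy, since score
#' opportunity scales with the number of scan positions); within each bin
#' scores are centred and scaled.  The default location/scale pair is
#' median and MAD (SD-consistent), which coincides with mean/SD under the
#' null but keeps genuine sweep outliers from inflating the bin scale --
#' essential when sweeps occupy a non-negligible gene fraction (see
#' vignette).  `method = "moment"` uses bin mean/SD; `method = "rank"`
#' maps within-bin ranks through the normal quantile function (which caps
#' attainable significance and is therefore not the default).  Bins with
#' zero scale yield `z = 0`.
#'
#' @param raw numeric raw scores.
#' @param win_counts integer window counts (same length).
#' @param n_bins number of bins (reduced with a warning if there are fewer
#'   than `5 * n_bins` genes).
#' @param method `"robust"` (median/MAD, default), `"moment"` (mean/SD) or
#'   `"rank"`.
#' @return numeric z scores.
#' @export
length_standardize <- function(raw, win_counts, n_bins = 20L,
                               method = c("robust", "moment", "rank")) {
  method <- match.arg(method)
  m <- length(raw)
  if (m < 5L * n_bins) {
    n_bins <- max(1L, m %/% 5L)
    warning("fewer than 5 genes per bin: reducing to ", n_bins, " bins")
  }
  ## bin edges are window-count quantiles, so genes with equal window
  ## count always share a bin: binning is order-independent and never
  ## splits ties by score (which would absorb real signal into bin means)
  edges <- unique(stats::quantile(win_counts,
                                  probs = seq(0, 1,
                                              length.out = n_bins + 1),
                                  type = 1))
  bin <- findInterval(win_counts, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  z <- numeric(m)
  for (b in unique(bin)) {
    i <- which(bin == b)
    if (method == "rank") {
      z[i] <- stats::qnorm((rank(raw[i], ties.method = "average") - 0.5) /
                             length(i))
      next
    }
    if (method == "robust") {
      mu <- stats::median(raw[i])
      sd <- stats::mad(raw[i])
    } else {
      mu <- mean(raw[i])
      sd <- stats::sd(raw[i])
    }
    z[i] <- if (is.na(sd) || sd == 0) 0 else (raw[i] - mu) / sd
  }
  z
}

#' Upper-tail P-values from z scores
#'
#' One-sided: sweeps only inflate the CLR, so evidence is in the upper tail
#' of the standard normal.
#' @param z numeric z scores.
#' @export
pvalues_from_z <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Storey q-values
#'
#' \eqn{\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m)) }, then the
#' usual step-up construction
#' \eqn{q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)} / j}.
#'
#' @param p P-values in `[0, 1]`.
#' @param lambda tuning constant for \eqn{\pi_0} (fixed 0.5 default; no
#'   spline, for determinism).
#' @return q-values in the original order.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Gene score pipeline for one population
#'
#' Convenience wrapper: assign, standardise, P, q.
#' @inheritParams gene_score_assign
#' @param population label attached to the output.
#' @param n_bins passed to [length_standardize()].
#' @return data.frame `gene`, `population`, `chrom`, `midpoint`, `raw_max`,
#'   `win_count`, `z`, `p`, `q`.
#' @export
gene_scores <- function(track, genes, population = "pop", flank = 50e3,
                        n_bins = 20L) {
  gs <- gene_score_assign(track, genes, flank)
  z <- length_standardize(gs$raw_max, gs$win_count, n_bins)
  p <- pvalues_from_z(z)
  q <- storey_qvalues(p)
  out <- data.frame(gene = gs$gene, population = population,
                    chrom = gs$chrom, midpoint = gs$midpoint,
                    raw_max = gs$raw_max, win_count = gs$win_count,
                    z = z, p = p, q = q)
  attr(out, "dropped") <- attr(gs, "dropped")
  out
}
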