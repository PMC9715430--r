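## Composite likelihood ratio scan for fixed hard sweeps, after the
## SweepFinder model: the expected SFS under a sweep is obtained from the
## genome-wide background SFS through the lineage escape probability, and the
## CLR contrasts the maximised sweep model against the same construction at
## p_e = 1 (which guarantees CLR >= 0 by nesting).

#' Lineage escape probability
#'
#' Probability that a lineage sampled at distance `d` (bp) from the selected
#' site recombines off the sweeping haplotype before coalescing into it,
#' \eqn{p_e = 1 - \exp(-\alpha d)}, with `alpha` the composite sweep
#' intensity per bp.
#'
#' @param alpha sweep intensity per bp (> 0).
#' @param d distance in bp (>= 0).
#' @return escape probability in `[0, 1)`.
#' @export
escape_probability <- function(alpha, d) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(d < 0)) stop("d must be >= 0")
  -expm1(-alpha * d)
}

#' Expected SFS under a hard sweep, conditional on the background SFS
#'
#' Mixture construction: the pre-sweep derived frequency is `f = j/n_ref`
#' with probability `bg$probs[j]`; each of `n` sampled lineages escapes the
#' sweep independently with probability `p_e` and then carries the derived
#' allele with probability `f`, while all non-escapees inherit the single
#' hitchhiking haplotype's allele (one draw at probability `f`).  The
#' resulting derived-count distribution is restricted to polymorphic classes
#' and renormalised.
#'
#' @param bg a [background_sfs()].
#' @param n site sample size, `2 <= n <= bg$n_ref`.
#' @param p_e escape probability in `[0, 1]`.
#' @param folded fold classes `j` and `n - j` (defaults to the background's
#'   polarisation).
#' @return list with `probs` (classes `1..n-1`, or folded classes) and
#'   `retention`, the polymorphic-retention probability before
#'   renormalisation.
#' @export
expected_sweep_sfs <- function(bg, n, p_e, folded = bg$folded) {
  stopifnot(inherits(bg, "background_sfs"))
  if (p_e < 0 || p_e > 1) stop("p_e must be in [0, 1]")
  if (n < 2 || n > bg$n_ref) stop("n must be in [2, n_ref]")
  .sweep_sfs_cpp(bg$probs, bg$n_ref, as.integer(n), p_e, folded)
}

#' Precompute CLR lookup tables for a background spectrum
#'
#' Class log-probabilities for every sample size in `n_values` on a log-
#' spaced grid of `w = alpha * d`, plus the `p_e = 1` null column.  Reused
#' across replicates/chromosomes scanned against the same background.
#'
#' @param bg a [background_sfs()].
#' @param n_values integer vector of sample sizes to tabulate (default
#'   `min_n .. n_ref`).
#' @param n_bins number of `w` bins.
#' @param w_min,w_max range of tabulated `w = alpha * d`; `w >= w_max` is
#'   treated as `p_e = 1`.
#' @return opaque table list consumed by [clr_scan()].
#' @export
clr_tables <- function(bg, n_values = NULL, n_bins = 96L, w_min = 1e-8,
                       w_max = 30) {
  stopifnot(inherits(bg, "background_sfs"))
  if (is.null(n_values)) n_values <- seq(max(2L, bg$min_n), bg$n_ref)
  .clr_tables_cpp(bg$probs, bg$n_ref, as.integer(n_values), bg$folded,
                  as.integer(n_bins), w_min, w_max)
}

#' Default log-spaced sweep-intensity search grid
#' @param alpha_min,alpha_max grid range (per bp).
#' @param n_alpha number of points.
#' @export
alpha_grid_default <- function(alpha_min = 1e-8, alpha_max = 1e-2,
                               n_alpha = 40L) {
  exp(seq(log(alpha_min), log(alpha_max), length.out = n_alpha))
}

## prepare per-site class/table indices; sites with n > n_ref are
## hypergeometrically downsampled once (uses the R RNG, hence seed-stable)
.clr_prepare_sites <- function(records, bg, tables) {
  rec <- records[records$x > 0 & records$x < records$n, , drop = FALSE]
  rec <- rec[rec$n >= max(2L, bg$min_n), , drop = FALSE]
  over <- which(rec$n > bg$n_ref)
  if (length(over)) {
    rec$x[over] <- stats::rhyper(length(over), rec$x[over],
                                 rec$n[over] - rec$x[over], bg$n_ref)
    rec$n[over] <- bg$n_ref
    rec <- rec[rec$x > 0 & rec$x < rec$n, , drop = FALSE]
  }
  rec <- rec[order(rec$position), , drop = FALSE]
  k <- if (bg$folded) pmin(rec$x, rec$n - rec$x) else rec$x
  nidx <- match(rec$n, tables$n_values)
  if (anyNA(nidx)) stop("sample size missing from CLR tables")
  list(pos = rec$position, k = as.integer(k), nidx = as.integer(nidx),
       n_sites = nrow(rec))
}

#' Composite likelihood ratio scan of one region
#'
#' At each grid position the composite log likelihood of the observed
#' polymorphic site classes is maximised over the sweep intensity `alpha`
#' (coarse log-spaced grid plus golden-section refinement, ties toward
#' smaller `alpha`) and contrasted against the nested null at `p_e = 1`:
#' \eqn{CLR = 2 (\max_\alpha L(\alpha) - L_0) \ge 0}.
#'
#' @param records allele-frequency records (see [site_allele_counts()]).
#' @param bg a [background_sfs()].
#' @param grid_positions scan positions (bp).
#' @param alpha_grid coarse search grid (default [alpha_grid_default()]).
#' @param radius site inclusion radius around each grid position (bp).
#' @param min_sites minimum polymorphic sites required (region skipped with
#'   a warning below this).
#' @param tables optional precomputed [clr_tables()].
#' @param refine_iter golden-section iterations (0 disables refinement).
#' @param refine_points pre-scan points per refined bracket (the
#'   interpolated likelihood is piecewise linear in log alpha; the
#'   pre-scan locates the active linear segment before polishing).
#' @return data.frame with `position`, `clr`, `alpha_hat`.
#' @export
clr_scan <- function(records, bg, grid_positions,
                     alpha_grid = alpha_grid_default(), radius = 200e3,
                     min_sites = 20L, tables = NULL, refine_iter = 20L,
                     refine_points = 32L) {
  stopifnot(inherits(bg, "background_sfs"))
  if (is.null(tables)) {
    nv <- sort(unique(pmin(records$n, bg$n_ref)))
    nv <- nv[nv >= max(2L, bg$min_n)]
    tables <- clr_tables(bg, n_values = nv)
  }
  st <- .clr_prepare_sites(records, bg, tables)
  if (st$n_sites < min_sites) {
    warning(sprintf("only %d polymorphic sites (< %d): region skipped",
                    st$n_sites, min_sites))
    return(data.frame(position = numeric(0), clr = numeric(0),
                      alpha_hat = numeric(0)))
  }
  res <- .clr_scan_cpp(st$pos, st$k, st$nidx, tables$tables,
                       as.numeric(grid_positions), as.numeric(alpha_grid),
                       radius, tables$n_bins, tables$w_min, tables$w_max,
                       as.integer(refine_iter), as.integer(refine_points))
  data.frame(position = as.numeric(grid_positions), clr = res$clr,
             alpha_hat = res$alpha_hat)
}

#' Genome-wide CLR scan at regular intervals
#'
#' Runs [clr_scan()] per chromosome on a regular grid (default every 1 kb);
#' sites never cross chromosome boundaries.
#'
#' @inheritParams clr_scan
#' @param grid_step spacing of scan positions in bp.
#' @param out_tsv optional path: writes the track as TSV
#'   (`chrom position clr alpha_hat`).
#' @return data.frame with `chrom`, `position`, `clr`, `alpha_hat`.
#' @export
clr_genome_scan <- function(records, bg, grid_step = 1000,
                            alpha_grid = alpha_grid_default(),
                            radius = 200e3, min_sites = 20L, tables = NULL,
                            out_tsv = NULL) {
  if (is.null(tables)) tables <- clr_tables(bg)
  out <- list()
  for (ch in unique(records$chrom)) {
    rec <- records[records$chrom == ch, , drop = FALSE]
    if (nrow(rec) == 0) next
    lo <- min(rec$position)
    hi <- max(rec$position)
    grid <- seq(ceiling(lo / grid_step) * grid_step, hi, by = grid_step)
    if (length(grid) == 0) next
    tr <- clr_scan(rec, bg, grid, alpha_grid, radius, min_sites, tables)
    if (nrow(tr)) out[[ch]] <- cbind(chrom = ch, tr)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), position = numeric(0),
               clr = numeric(0), alpha_hat = numeric(0))
  rownames(res) <- NULL
  if (!is.null(out_tsv))
    utils::write.table(res, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
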