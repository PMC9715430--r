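## Aggregation of outlier genes into candidate sweep regions, merging across
## populations, the two-tier q threshold, presence matrices, sweep antiquity
## classification against a reference panel, and presence-by-group tests.

#' Collapse neighbouring outlier genes into clusters
#'
#' Single-linkage chaining per chromosome: genes whose midpoints are less
#' than `max_dist` apart join one cluster.
#'
#' @param outliers data.frame with `gene`, `chrom`, `midpoint` (one
#'   population's outliers).
#' @param max_dist collapse distance in bp (default 1 Mb, the most liberal
#'   intergene distance).
#' @return the input with an integer `cluster` column.
#' @export
collapse_outlier_genes <- function(outliers, max_dist = 1e6) {
  if (nrow(outliers) == 0) {
    outliers$cluster <- integer(0)
    return(outliers)
  }
  ord <- order(outliers$chrom, outliers$midpoint)
  out <- outliers[ord, , drop = FALSE]
  newc <- c(TRUE, diff(out$midpoint) >= max_dist |
              out$chrom[-1] != out$chrom[-nrow(out)])
  out$cluster <- cumsum(newc)
  out
}

#' Merge per-population clusters into sweep regions
#'
#' Transitive closure of the shares-a-gene relation across populations
#' (union-find): clusters from different populations sharing at least one
#' gene are a single historical sweep.
#'
#' @param clusters data.frame with `gene`, `chrom`, `midpoint`,
#'   `population`, `cluster` (cluster ids unique within population).
#' @return data.frame mapping `gene` (unique) to a `region` id, with
#'   `chrom` and `midpoint`.
#' @export
merge_across_populations <- function(clusters) {
  if (nrow(clusters) == 0)
    return(data.frame(gene = character(0), chrom = character(0),
                      midpoint = numeric(0), region = integer(0)))
  key <- paste(clusters$population, clusters$cluster, sep = "#")
  ukey <- unique(key)
  parent <- seq_along(ukey)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ki <- match(key, ukey)
  for (g in unique(clusters$gene)) {
    ids <- unique(ki[clusters$gene == g])
    if (length(ids) > 1) {
      r1 <- find(ids[1])
      for (j in ids[-1]) {
        r2 <- find(j)
        if (r1 != r2) parent[r2] <- r1
        r1 <- find(ids[1])
      }
    }
  }
  root <- vapply(seq_along(ukey), find, integer(1))
  reg_of_key <- match(root, sort(unique(root)))
  df <- data.frame(gene = clusters$gene, chrom = clusters$chrom,
                   midpoint = clusters$midpoint,
                   region = reg_of_key[ki])
  df <- df[!duplicated(df$gene), , drop = FALSE]
  df[order(df$region, df$midpoint), ]
}

#' Build candidate sweep regions from per-population gene score tables
#'
#' Regions are seeded at the permissive threshold (`q < q_build`), collapsed
#' per population ([collapse_outlier_genes()]), merged across populations
#' ([merge_across_populations()]), and then filtered by the stringent
#' two-tier rule: a region is kept iff at least one member gene has
#' `q < q_define` in at least one defining population (populations with
#' `n_eff < 10` or flagged as out-of-scope are excluded from the defining
#' set).
#'
#' @param score_table row-bound [gene_scores()] tables over populations.
#' @param q_build permissive build threshold (default 0.1).
#' @param q_define stringent defining threshold (default 0.01).
#' @param max_dist collapse distance in bp.
#' @param defining_populations populations allowed to define a sweep
#'   (default: all present).
#' @return data.frame, one row per region: `region`, `chrom`, `start`,
#'   `end` (1-based inclusive span of member-gene midpoints extended to
#'   gene bounds if provided), `genes` (comma-separated), `n_genes`,
#'   `min_q`, `defining_population`.
#' @export
sweep_regions <- function(score_table, q_build = 0.1, q_define = 0.01,
                          max_dist = 1e6, defining_populations = NULL) {
  if (is.null(defining_populations))
    defining_populations <- unique(score_table$population)
  out <- score_table[score_table$q < q_build, , drop = FALSE]
  if (nrow(out) == 0) return(empty_region_table())
  clusters <- do.call(rbind, lapply(split(out, out$population), function(d)
    collapse_outlier_genes(d, max_dist)))
  merged <- merge_across_populations(clusters)
  if (nrow(merged) == 0) return(empty_region_table())
  regions <- lapply(split(merged, merged$region), function(mg) {
    member <- score_table[score_table$gene %in% mg$gene, , drop = FALSE]
    def <- member[member$population %in% defining_populations, , drop = FALSE]
    minq <- if (nrow(def)) min(def$q) else Inf
    data.frame(region = mg$region[1], chrom = mg$chrom[1],
               start = min(mg$midpoint), end = max(mg$midpoint),
               genes = paste(sort(unique(mg$gene)), collapse = ","),
               n_genes = length(unique(mg$gene)), min_q = minq,
               defining_population = if (nrow(def))
                 def$population[which.min(def$q)] else NA_character_)
  })
  tab <- do.call(rbind, regions)
  tab <- tab[tab$min_q < q_define, , drop = FALSE]
  if (nrow(tab) == 0) return(empty_region_table())
  tab$region <- seq_len(nrow(tab))
  tab$id <- sprintf("%s:%.1f-%.1f", tab$chrom, tab$start / 1e6,
                    tab$end / 1e6)
  rownames(tab) <- NULL
  tab
}

empty_region_table <- function() {
  data.frame(region = integer(0), chrom = character(0), start = numeric(0),
             end = numeric(0), genes = character(0), n_genes = integer(0),
             min_q = numeric(0), defining_population = character(0),
             id = character(0))
}

#' Two-tier filter on prebuilt regions
#'
#' Keep regions whose best member-gene q in a defining population is below
#' `q_define`.
#' @param regions region table (with `min_q`).
#' @param q_define stringent threshold (default 0.01).
#' @export
two_tier_filter <- function(regions, q_define = 0.01) {
  regions[regions$min_q < q_define, , drop = FALSE]
}

#' Population presence matrix for sweep regions
#'
#' `presence[region, population]` is TRUE iff any member gene has
#' `q < q_present` in that population.  Populations failing the effective-
#' sample-size rule are excluded (no column).
#'
#' @param regions region table from [sweep_regions()].
#' @param score_table row-bound [gene_scores()] tables.
#' @param q_present presence threshold (default 0.05).
#' @param populations populations (columns); default all in `score_table`.
#' @return logical matrix regions x populations.
#' @export
population_presence_matrix <- function(regions, score_table,
                                       q_present = 0.05,
                                       populations = NULL) {
  if (is.null(populations)) populations <- unique(score_table$population)
  M <- matrix(FALSE, nrow(regions), length(populations),
              dimnames = list(regions$id, populations))
  for (i in seq_len(nrow(regions))) {
    genes <- strsplit(regions$genes[i], ",", fixed = TRUE)[[1]]
    sub <- score_table[score_table$gene %in% genes &
                         score_table$q < q_present, , drop = FALSE]
    M[i, intersect(unique(sub$population), populations)] <- TRUE
  }
  M
}

#' Classify sweep antiquity against a reference sample panel
#'
#' Diagnostic alleles are the major alleles of the defining population at
#' the SNPs flanking the region peak.  For each reference sample (oldest
#' first) the match fraction over its covered diagnostic sites is computed;
#' the sample carries the sweep if it covers at least
#' `min_covered_fraction` of the diagnostics and matches at least
#' `match_threshold` of the covered ones.  The class is the oldest carrying
#' sample; if none carries, the youngest class (which pools sweeps not seen
#' in any reference sample).
#'
#' @param diagnostic data.frame with `position` and `allele` (0/1 major
#'   allele of the defining population).
#' @param panel named list: per reference sample a data.frame with
#'   `position`, `call` (0/1/NA); list order = oldest first.
#' @param match_threshold minimum match fraction (default 0.9).
#' @param min_covered_fraction minimum covered fraction (default 0.5).
#' @return list with `class` (name of the oldest carrying sample, or the
#'   youngest panel name if none) and per-sample diagnostics.
#' @export
sweep_age_classify <- function(diagnostic, panel, match_threshold = 0.9,
                               min_covered_fraction = 0.5) {
  if (nrow(diagnostic) == 0) return(list(class = NA_character_,
                                         detail = NULL))
  detail <- lapply(names(panel), function(nm) {
    s <- panel[[nm]]
    idx <- match(diagnostic$position, s$position)
    call <- s$call[idx]
    covered <- !is.na(call)
    cf <- mean(covered)
    mf <- if (any(covered))
      mean(call[covered] == diagnostic$allele[covered]) else NA_real_
    carries <- isTRUE(cf >= min_covered_fraction && mf >= match_threshold)
    data.frame(sample = nm, covered_fraction = cf, match_fraction = mf,
               carries = carries)
  })
  detail <- do.call(rbind, detail)
  cls <- if (any(detail$carries)) detail$sample[which(detail$carries)[1]]
  else detail$sample[nrow(detail)]
  list(class = cls, detail = detail)
}

#' Likelihood-ratio test of sweep presence against population groups
#'
#' Bernoulli log-likelihood with group-specific presence probabilities
#' versus a common probability; group MLEs are the group means (exact at
#' the boundary), LRT = 2 * delta logL, P from chi-square with G - 1 df.
#'
#' @param presence logical/0-1 vector (sweeps in one age class x
#'   populations, flattened) or matrix.
#' @param groups group label per entry.
#' @return list `lrt`, `p_value`, `df`, `group_props`.
#' @export
presence_group_test <- function(presence, groups) {
  y <- as.numeric(presence)
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (length(y) != length(g)) stop("presence and groups lengths differ")
  bern_ll <- function(y) {
    p <- mean(y)
    if (p == 0 || p == 1) return(0)  # boundary MLE: likelihood 1
    sum(y) * log(p) + sum(1 - y) * log(1 - p)
  }
  l0 <- bern_ll(y)
  l1 <- sum(vapply(levels(g), function(lv) bern_ll(y[g == lv]), 0))
  lrt <- max(0, 2 * (l1 - l0))
  df <- nlevels(g) - 1
  list(lrt = lrt, p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
       df = df,
       group_props = vapply(levels(g), function(lv) mean(y[g == lv]), 0))
}

#' Peak position and sweep intensity for a region
#'
#' Maximum CLR across the defining populations' tracks within the region
#' interval; ties broken toward the smaller coordinate.
#'
#' @param region one row of a region table (`chrom`, `start`, `end`).
#' @param tracks named list of per-population scan tracks
#'   (data.frames with `chrom`, `position`, `clr`, `alpha_hat`).
#' @param flank extra bp considered around the region interval.
#' @return list `position`, `alpha_hat`, `clr`, `population`.
#' @export
estimate_selection_peak <- function(region, tracks, flank = 50e3) {
  best <- NULL
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    sel <- tr$chrom == region$chrom &
      tr$position >= region$start - flank &
      tr$position <= region$end + flank
    if (!any(sel)) next
    sub <- tr[sel, , drop = FALSE]
    sub <- sub[order(-sub$clr, sub$position), , drop = FALSE]
    cand <- list(position = sub$position[1], alpha_hat = sub$alpha_hat[1],
                 clr = sub$clr[1], population = nm)
    if (is.null(best) || cand$clr > best$clr ||
        (cand$clr == best$clr && cand$position < best$position))
      best <- cand
  }
  best
}

#' Write sweep regions as a BED file
#'
#' Converts the 1-based inclusive region intervals to BED's 0-based
#' half-open convention at the boundary.
#' @param regions region table.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start - 1),
                    end = as.integer(regions$end), name = regions$id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
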