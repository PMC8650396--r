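# Per-site differential methylation between two groups of genomes, BH
# correction, and cross-assay DMA/DM4+ concordance metrics.
#
# The per-site model is a binomial GLM of (n_meth, n_unmeth) on the group
# indicator.  With a single binary covariate the MLE has a closed form (the
# fitted proportions are the group-pooled proportions), so the deviance
# likelihood-ratio statistic is computed directly from pooled counts:
# identical to an IRLS fit, but vectorisable over sites and exact under
# separation (0 log 0 := 0; no coefficient blows up because only fitted
# proportions enter the likelihood).

# binomial log-likelihood term m*log(p) + u*log(1-p) with 0*log(0) = 0
.bll <- function(m, u, p) {
  t1 <- ifelse(m > 0, m * log(p), 0)
  t2 <- ifelse(u > 0, u * log(1 - p), 0)
  t1 + t2
}

#' Coverage filter for two-group differential methylation
#'
#' A site is retained iff each group has at least `min_samples` members
#' covering it at `min_cov` or more.
#'
#' @param group1,group2 lists of MethylCallSets (one per genome).
#' @param min_cov minimum per-sample coverage (default 5).
#' @param min_samples minimum qualifying samples per group (default 2).
#' @return data.table of retained (chrom, start).
#' @export
site_filter <- function(group1, group2, min_cov = 5L, min_samples = 2L) {
  .assert(length(group1) >= min_samples && length(group2) >= min_samples,
          "each group needs at least min_samples call sets")
  count_ok <- function(grp) {
    long <- rbindlist(lapply(grp, function(x)
      x$records[n_meth + n_unmeth >= min_cov, .(chrom, start)]))
    long[, .(n_ok = .N), by = .(chrom, start)]
  }
  c1 <- count_ok(group1); c2 <- count_ok(group2)
  keep <- merge(c1[n_ok >= min_samples], c2[n_ok >= min_samples],
                by = c("chrom", "start"))
  setorder(keep, chrom, start)
  keep[, .(chrom, start)]
}

#' Likelihood-ratio test for one site
#'
#' Binomial GLM deviance test of group membership against the intercept-only
#' model: statistic = 2 (ll_full - ll_null), chi-squared with 1 df.  Sites
#' that are all-zero or all-full in both groups give statistic 0, p = 1.
#'
#' @param n_meth,n_unmeth integer vectors, one entry per sample.
#' @param group factor/vector with exactly two levels.
#' @return list: `stat`, `p`, `p1`, `p2` (group-pooled proportions).
#' @export
fit_site <- function(n_meth, n_unmeth, group) {
  g <- as.integer(factor(group))
  .assert(length(unique(g)) == 2L, "group must have exactly two levels")
  m1 <- sum(n_meth[g == 1L]); u1 <- sum(n_unmeth[g == 1L])
  m2 <- sum(n_meth[g == 2L]); u2 <- sum(n_unmeth[g == 2L])
  p1 <- m1 / (m1 + u1); p2 <- m2 / (m2 + u2)
  p0 <- (m1 + m2) / (m1 + u1 + m2 + u2)
  stat <- 2 * (.bll(m1, u1, p1) + .bll(m2, u2, p2) -
                 .bll(m1 + m2, u1 + u2, p0))
  stat <- max(stat, 0)
  list(stat = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       p1 = p1, p2 = p2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q for the i-th smallest p is min over j >= i of (m/j) p_(j), capped at 1
#' and mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  .assert(all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(m / seq_len(m) * ps))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Percent methylation difference of group-pooled proportions
#'
#' @param n_meth,n_unmeth per-sample counts.
#' @param group two-level grouping.
#' @return p_group1 - p_group2, in \[-1, 1\].
#' @export
pmd <- function(n_meth, n_unmeth, group) {
  g <- as.integer(factor(group))
  .assert(length(unique(g)) == 2L, "group must have exactly two levels")
  p1 <- sum(n_meth[g == 1L]) / sum(n_meth[g == 1L] + n_unmeth[g == 1L])
  p2 <- sum(n_meth[g == 2L]) / sum(n_meth[g == 2L] + n_unmeth[g == 2L])
  p1 - p2
}

#' Two-group differential methylation over all filtered sites
#'
#' Applies [site_filter()], fits the per-site binomial LRT (vectorised over
#' sites), adjusts p-values by Benjamini-Hochberg, and reports the percent
#' methylation difference of the group-pooled proportions.
#'
#' @param group1,group2 lists of MethylCallSets (one per genome).
#' @param min_cov,min_samples filter settings (defaults 5x, 2 samples).
#' @param alpha significance threshold on the adjusted values (default 0.05).
#' @return data.table of class `DMResult`: chrom, start, per-group pooled
#'   counts, `stat`, `p`, `q`, `pmd`, `significant`.
#' @export
dm_test <- function(group1, group2, min_cov = 5L, min_samples = 2L,
                    alpha = 0.05) {
  keep <- site_filter(group1, group2, min_cov, min_samples)
  pool <- function(grp) {
    long <- rbindlist(lapply(grp, function(x)
      x$records[, .(chrom, start, n_meth, n_unmeth)]))
    long[keep, on = c("chrom", "start"), nomatch = NULL][
      , .(m = sum(n_meth), u = sum(n_unmeth)), by = .(chrom, start)]
  }
  g1 <- pool(group1); g2 <- pool(group2)
  dt <- merge(g1, g2, by = c("chrom", "start"), suffixes = c("1", "2"))
  p1 <- dt$m1 / (dt$m1 + dt$u1)
  p2 <- dt$m2 / (dt$m2 + dt$u2)
  p0 <- (dt$m1 + dt$m2) / (dt$m1 + dt$u1 + dt$m2 + dt$u2)
  stat <- pmax(0, 2 * (.bll(dt$m1, dt$u1, p1) + .bll(dt$m2, dt$u2, p2) -
                         .bll(dt$m1 + dt$m2, dt$u1 + dt$u2, p0)))
  dt[, `:=`(stat = stat,
            p = pchisq(stat, df = 1L, lower.tail = FALSE),
            pmd = p1 - p2)]
  dt[, q := bh_adjust(p)]
  dt[, significant := q < alpha]
  setorder(dt, chrom, start)
  setattr(dt, "class", c("DMResult", class(dt)))
  dt[]
}

#' Cross-assay concordance of differentially methylated site sets
#'
#' Given each assay's DMA set over a common analyzed universe, reports per
#' assay: the DMA size, the fraction of its DMA sites called by no other
#' assay (a pseudo false-positive rate), specificity (fraction of DMA also
#' in DMk+, the sites called by >= k assays in total) and sensitivity
#' (fraction of DMk+ recovered).  The "k other assays" variant replaces
#' membership of DMk+ by "called by >= k - 1 of the *other* assays", the
#' phrasing used when an assay is compared against its peers.
#'
#' @param dma_sets named list of character site-id vectors (one per assay).
#' @param universe character vector of all analyzed site ids.
#' @param k DMk+ threshold (default 4).
#' @return list of class `ConcordanceReport`: `per_assay` (data.table),
#'   `dmk_sizes` (named sizes of DM1+..DMn+), `k`, `n_universe`.
#' @export
concordance <- function(dma_sets, universe, k = 4L) {
  .assert(length(dma_sets) >= 2L, "need at least two assays")
  .assert(length(universe) > 0L, "empty site universe")
  nm <- names(dma_sets) %||% paste0("assay", seq_along(dma_sets))
  .assert(all(unlist(dma_sets) %in% universe),
          "DMA sites outside the analyzed universe")
  M <- vapply(dma_sets, function(s) universe %in% s,
              logical(length(universe)))
  deg <- rowSums(M)
  n_assay <- length(dma_sets)
  dmk_sizes <- setNames(vapply(seq_len(n_assay), function(j) sum(deg >= j), 0L),
                        paste0("DM", seq_len(n_assay), "+"))
  dmk <- deg >= k
  per_assay <- rbindlist(lapply(seq_len(n_assay), function(i) {
    in_a <- M[, i]
    n_dma <- sum(in_a)
    other <- deg - in_a
    data.table(
      assay = nm[i], n_dma = n_dma,
      unique_fraction = if (n_dma) sum(in_a & deg == 1L) / n_dma else NA_real_,
      specificity = if (n_dma) sum(in_a & dmk) / n_dma else NA_real_,
      sensitivity = if (sum(dmk)) sum(in_a & dmk) / sum(dmk) else NA_real_,
      specificity_other = if (n_dma) sum(in_a & other >= k - 1L) / n_dma
                          else NA_real_,
      sensitivity_other = if (sum(other >= k - 1L))
        sum(in_a & other >= k - 1L) / sum(other >= k - 1L) else NA_real_)
  }))
  structure(list(per_assay = per_assay[], dmk_sizes = dmk_sizes, k = k,
                 n_universe = length(universe)),
            class = "ConcordanceReport")
}

#' Cross-tabulate DMA agreement by coverage percentile bins
#'
#' For one assay's DMA sites: rows are the number of assays identifying each
#' site (1..n), columns are bins of the site's median coverage between its
#' 5th and 95th percentiles (sites outside that range are excluded).
#'
#' @param dma_sets named list of site-id vectors.
#' @param median_coverage named numeric vector: per-site median coverage
#'   across samples.
#' @param n_bins number of equal-width coverage bins (default 10).
#' @param probs percentile bounds (default `c(0.05, 0.95)`).
#' @return named list per assay: `table` (agreement x bin contingency
#'   matrix), `breaks`, `bounds`.
#' @export
agreement_by_coverage <- function(dma_sets, median_coverage, n_bins = 10L,
                                  probs = c(0.05, 0.95)) {
  nm <- names(dma_sets) %||% paste0("assay", seq_along(dma_sets))
  all_sites <- unique(unlist(dma_sets))
  .assert(all(all_sites %in% names(median_coverage)),
          "median coverage missing for some DMA sites")
  deg <- setNames(rep(0L, length(all_sites)), all_sites)
  for (s in dma_sets) deg[s] <- deg[s] + 1L
  out <- lapply(seq_along(dma_sets), function(i) {
    sites <- dma_sets[[i]]
    if (!length(sites)) return(list(table = NULL, breaks = NULL, bounds = NULL))
    cv <- median_coverage[sites]
    bounds <- .pctl(cv, probs)
    keep <- cv >= bounds[1] & cv <= bounds[2]
    breaks <- seq(bounds[1], bounds[2], length.out = n_bins + 1L)
    bin <- cut(cv[keep], breaks, include.lowest = TRUE)
    agree <- factor(deg[sites][keep], levels = seq_along(dma_sets))
    list(table = table(agreement = agree, coverage_bin = bin),
         breaks = breaks, bounds = bounds)
  })
  names(out) <- nm
  out
}

#' Array percent methylation difference via genome means
#'
#' Two-stage estimate equal (for balanced designs) to the group-effect
#' estimate of a mixed model with a random intercept per genome: average the
#' replicates within each genome, then average genome means within each
#' group; PMD is the difference of the two group means.  Genomes with no
#' replicate are omitted with a warning.
#'
#' @param bm BetaMatrix.
#' @param group1,group2 character vectors of cell-line names.
#' @return named numeric vector of per-site PMD (group1 - group2).
#' @export
array_pmd <- function(bm, group1, group2) {
  stopifnot(inherits(bm, "BetaMatrix"))
  genome_mean <- function(cl) {
    idx <- which(bm$sample_meta$cell_line == cl)
    if (!length(idx)) {
      warning("no replicates for genome ", cl, "; omitted")
      return(NULL)
    }
    rowMeans(bm$beta[, idx, drop = FALSE], na.rm = TRUE)
  }
  gmeans <- function(cls) {
    ms <- Filter(Negate(is.null), lapply(cls, genome_mean))
    .assert(length(ms) > 0L, "a group has no genomes with replicates")
    Reduce(`+`, ms) / length(ms)
  }
  out <- gmeans(group1) - gmeans(group2)
  setNames(as.numeric(out), bm$site_meta$probe_id)
}

#' Agreement between sequencing DMAs and array methylation differences
#'
#' Per assay: the fraction of its DMA sites at which the array shows an
#' absolute PMD of at least `threshold`; and the reverse, the fraction of
#' array sites with |PMD| >= threshold that the assay called DM.
#'
#' @param dma_sets named list of probe-id vectors (restricted to the common
#'   probe universe).
#' @param apmd named per-probe array PMD vector, as from [array_pmd()].
#' @param threshold absolute PMD cutoff (default 0.2).
#' @return data.table: assay, n_dma, `frac_dma_with_array_pmd`,
#'   `frac_array_pmd_in_dma`.
#' @export
array_seq_dm_agreement <- function(dma_sets, apmd, threshold = 0.2) {
  .assert(all(unlist(dma_sets) %in% names(apmd)),
          "DMA sites missing from the array PMD vector")
  big <- names(apmd)[abs(apmd) >= threshold]
  rbindlist(lapply(names(dma_sets), function(a) {
    s <- dma_sets[[a]]
    data.table(
      assay = a, n_dma = length(s),
      frac_dma_with_array_pmd = if (length(s)) mean(s %in% big) else NA_real_,
      frac_array_pmd_in_dma = if (length(big)) mean(big %in% s) else NA_real_)
  }))
}
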