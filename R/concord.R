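# Replicate reproducibility and cross-assay concordance.

# long table of (chrom, start, set index, beta, coverage) over a list of
# call sets, restricted to sites present in all of them
.common_long <- function(callsets) {
  long <- rbindlist(lapply(seq_along(callsets), function(i) {
    r <- callsets[[i]]$records
    data.table(chrom = r$chrom, start = r$start, set = i,
               beta = r$n_meth / (r$n_meth + r$n_unmeth),
               cov = r$n_meth + r$n_unmeth)
  }))
  long[, n_present := .N, by = .(chrom, start)]
  long[n_present == length(callsets)][, n_present := NULL][]
}

#' Standard deviation of beta values across replicates, by coverage
#'
#' For every site present in all replicates, the sample SD of the replicate
#' betas is paired with the replicates' mean coverage, then binned.
#'
#' @param callsets list of >= 2 replicate MethylCallSets.
#' @param bin_width coverage bin width (default 1x).
#' @return list: `sites` (per-site mean_cov, sd_beta) and `binned`
#'   (data.table coverage_bin, mean_sd, n).
#' @export
replicate_sd <- function(callsets, bin_width = 1) {
  .assert(is.list(callsets) && length(callsets) >= 2L,
          "need at least two replicate call sets")
  long <- .common_long(callsets)
  sites <- long[, .(mean_cov = mean(cov), sd_beta = sd(beta)),
                by = .(chrom, start)]
  sites[, coverage_bin := bin_width * floor(mean_cov / bin_width)]
  binned <- sites[, .(mean_sd = mean(sd_beta), n = .N), by = coverage_bin]
  setorder(binned, coverage_bin)
  list(sites = sites[], binned = binned[])
}

#' Expected replicate SD curve under the iid binomial model
#'
#' If replicate betas at a site are independent estimates of a common
#' proportion p from c observations each, their variance is p(1-p)/c.  The
#' curve reports sqrt(mean over sites of p̂(1-p̂)) / sqrt(c) on a coverage
#' grid, with p̂ pooled across replicates (square root of the expected
#' variance; the small-K bias of E\[sqrt\] is validated by simulation in the
#' test suite).
#'
#' @param pooled_p per-site pooled methylation proportions.
#' @param coverage_grid coverage values at which to evaluate the curve.
#' @return data.table of class `ExpectedSdCurve`: `coverage`, `expected_sd`;
#'   attribute `"mean_pq"` stores the pooled p(1-p) summary.
#' @export
expected_sd_curve <- function(pooled_p, coverage_grid) {
  .assert(length(pooled_p) > 0L, "no pooled proportions supplied")
  .assert(all(pooled_p >= 0 & pooled_p <= 1), "proportions must lie in [0,1]")
  mean_pq <- mean(pooled_p * (1 - pooled_p))
  out <- data.table(coverage = sort(coverage_grid),
                    expected_sd = sqrt(mean_pq / sort(coverage_grid)))
  setattr(out, "mean_pq", mean_pq)
  setattr(out, "class", c("ExpectedSdCurve", class(out)))
  out[]
}

#' Pairwise Pearson correlation of methylation estimates
#'
#' Correlations over the sites common to all call sets.  The intermediate
#' stratum restricts to sites whose methylation is between 20 and 80%,
#' judged either on the mean of each pair's betas (`"pair_mean"`, default:
#' symmetric in the pair) or on one designated reference set
#' (`"reference"`).
#'
#' @param callsets named list of >= 2 MethylCallSets.
#' @param stratum `"all"` or `"intermediate"` (betas in \[0.2, 0.8\]).
#' @param stratum_on `"pair_mean"` or `"reference"`.
#' @param reference index/name of the reference set for
#'   `stratum_on = "reference"`.
#' @param bounds stratum bounds (inclusive).
#' @return symmetric correlation matrix with unit diagonal; NA entries where
#'   fewer than 3 sites remain.
#' @export
beta_correlation_matrix <- function(callsets, stratum = c("all", "intermediate"),
                                    stratum_on = c("pair_mean", "reference"),
                                    reference = 1L, bounds = c(0.2, 0.8)) {
  stratum <- match.arg(stratum)
  stratum_on <- match.arg(stratum_on)
  .assert(length(callsets) >= 2L, "need at least two call sets")
  long <- .common_long(callsets)
  wide <- dcast(long, chrom + start ~ set, value.var = "beta")
  B <- as.matrix(wide[, -(1:2)])
  nm <- names(callsets) %||% paste0("set", seq_along(callsets))
  colnames(B) <- nm
  k <- ncol(B)
  M <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(M) <- 1
  ref_idx <- if (is.character(reference)) match(reference, nm) else reference
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    keep <- if (stratum == "all") rep(TRUE, nrow(B))
    else {
      s <- switch(stratum_on,
                  pair_mean = (B[, i] + B[, j]) / 2,
                  reference = B[, ref_idx])
      s >= bounds[1] & s <= bounds[2]
    }
    if (sum(keep) >= 3L) M[i, j] <- M[j, i] <- cor(B[keep, i], B[keep, j])
  }
  M
}

#' Pairwise rank correlation of per-site coverage
#'
#' Spearman correlation of coverage values over the common-site
#' intersection.
#'
#' @param callsets named list of >= 2 MethylCallSets.
#' @return symmetric matrix with unit diagonal.
#' @export
coverage_correlation <- function(callsets) {
  .assert(length(callsets) >= 2L, "need at least two call sets")
  long <- .common_long(callsets)
  wide <- dcast(long, chrom + start ~ set, value.var = "cov")
  C <- as.matrix(wide[, -(1:2)])
  nm <- names(callsets) %||% paste0("set", seq_along(callsets))
  colnames(C) <- nm
  if (nrow(C) < 3L) {
    M <- matrix(NA_real_, ncol(C), ncol(C), dimnames = list(nm, nm))
    diag(M) <- 1
    return(M)
  }
  cor(C, method = "spearman")
}

#' Site coverage intersections across assays
#'
#' Assigns every site (in the union) the exact subset of assays covering it
#' at >= `min_cov`, UpSet style.  Uniquely covered sites belong to exactly
#' one assay's subset; uniquely missed sites are absent from exactly one.
#'
#' @param callsets named list of >= 2 MethylCallSets.
#' @param min_cov coverage threshold (default 5).
#' @return list: `cells` (data.table subset/n), `unique_covered` and
#'   `unique_missed` (named lists of site data.tables per assay), and
#'   `membership` (data.table chrom/start + one logical column per assay).
#' @export
site_intersections <- function(callsets, min_cov = 5L) {
  .assert(length(callsets) >= 2L, "need at least two call sets")
  nm <- names(callsets) %||% paste0("set", seq_along(callsets))
  long <- rbindlist(lapply(seq_along(callsets), function(i) {
    r <- callsets[[i]]$records
    r[n_meth + n_unmeth >= min_cov, .(chrom, start, set = nm[i])]
  }))
  if (!nrow(long)) {
    return(list(cells = data.table(subset = character(), n = integer()),
                unique_covered = setNames(vector("list", length(nm)), nm),
                unique_missed = setNames(vector("list", length(nm)), nm),
                membership = data.table(chrom = character(), start = integer())))
  }
  memb <- dcast(long[, .(chrom, start, set, v = TRUE)],
                chrom + start ~ set, value.var = "v", fill = FALSE)
  for (a in setdiff(nm, names(memb))) memb[, (a) := FALSE]
  setcolorder(memb, c("chrom", "start", nm))
  M <- as.matrix(memb[, ..nm])
  key <- apply(M, 1L, function(z) paste(nm[z], collapse = "&"))
  cells <- as.data.table(table(subset = key))
  setnames(cells, "N", "n")
  deg <- rowSums(M)
  take <- function(keep) data.table(chrom = memb$chrom[keep],
                                    start = memb$start[keep])
  unique_covered <- lapply(nm, function(a) take(deg == 1L & M[, a]))
  unique_missed <- lapply(nm, function(a)
    take(deg == length(nm) - 1L & !M[, a]))
  names(unique_covered) <- names(unique_missed) <- nm
  list(cells = cells[], unique_covered = unique_covered,
       unique_missed = unique_missed, membership = memb[])
}

#' Annotate uniquely covered / missed sites
#'
#' Tabulates the gene-context feature labels of each assay's unique site set.
#'
#' @param unique_sets named list of site data.tables (chrom, start), e.g.
#'   `site_intersections()$unique_covered`.
#' @param annot AnnotationSet.
#' @return data.table: `assay`, `feature`, `n` (zero rows kept).
#' @export
unique_site_annotation <- function(unique_sets, annot) {
  all_labels <- c(.gene_precedence, "intergenic")
  rbindlist(lapply(names(unique_sets), function(a) {
    s <- unique_sets[[a]]
    if (is.null(s) || nrow(s) == 0L)
      return(data.table(assay = a, feature = all_labels, n = 0L))
    cs <- methyl_callset(data.table(chrom = s$chrom, start = s$start,
                                    end = s$start + 2L, strand = "*",
                                    context = "CpG", n_meth = 1L,
                                    n_unmeth = 0L))
    lab <- annotation_assign(cs, annot)
    tab <- lab[, .N, by = feature]
    out <- data.table(assay = a, feature = all_labels)
    out[tab, n := i.N, on = "feature"]
    out[is.na(n), n := 0L]
    out
  }))
}
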