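# Variance-partition evaluation of normalized beta matrices and the
# SNP-probe-derived low-variance site filter.
#
# Variance components for the crossed random-effects model
#   y = mu + a_factor1 + b_factor2 + e
# are estimated per site by Henderson's Method III: reductions in sums of
# squares R(a | mu, b) and R(b | mu, a) have expectations that are linear in
# (sigma_a^2, sigma_b^2, sigma_e^2) with coefficients that depend only on the
# design, so the whole sites x samples matrix is solved with three quadratic
# forms.  Deterministic, closed-form, and exact for balanced layouts.

# projection matrix onto the column space of X
.proj <- function(X) {
  qr_x <- qr(X)
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  tcrossprod(Q)
}

# design constants for Henderson III on a two-factor crossed layout
.h3_design <- function(f1, f2) {
  Za <- stats::model.matrix(~ f1 - 1)
  Zb <- stats::model.matrix(~ f2 - 1)
  n <- nrow(Za)
  one <- matrix(1, n, 1)
  P_full <- .proj(cbind(one, Za, Zb))
  P_1b <- .proj(cbind(one, Zb))
  P_1a <- .proj(cbind(one, Za))
  r_full <- qr(cbind(one, Za, Zb))$rank
  Qa <- P_full - P_1b
  Qb <- P_full - P_1a
  M <- diag(n) - P_full
  df_a <- r_full - qr(cbind(one, Zb))$rank
  df_b <- r_full - qr(cbind(one, Za))$rank
  df_e <- n - r_full
  # tr(Za' Q Za) = sum(Q * Za Za') for symmetric Q
  c_a <- sum(Qa * tcrossprod(Za))
  c_b <- sum(Qb * tcrossprod(Zb))
  if (df_e <= 0L) stop("no residual degrees of freedom: replicate the design")
  if (c_a < 1e-8 || c_b < 1e-8 || df_a == 0L || df_b == 0L)
    stop("factors are confounded (identical grouping); cannot partition variance")
  list(Qa = Qa, Qb = Qb, M = M, c_a = c_a, c_b = c_b,
       df_a = df_a, df_b = df_b, df_e = df_e)
}

#' Per-site variance partition of a beta matrix
#'
#' Decomposes each site's beta-value variance into fractions explained by two
#' crossed sample factors (default cell line and lab) and a residual, using
#' method-of-moments estimates of the crossed random-effects components
#' (negative estimates clamped to zero; fractions renormalized to sum to 1).
#' Sites with missing values are estimated on their complete cases, grouped
#' by missingness pattern; sites with constant observed values get residual
#' fraction 1.
#'
#' @param bm BetaMatrix (or a plain matrix plus `sample_meta`).
#' @param factors two column names of the sample metadata
#'   (default `c("cell_line", "lab")`; use `c("cell_line", "assay")` for the
#'   merged sequencing/array mode).
#' @param sample_meta optional sample metadata when `bm` is a bare matrix.
#' @return data.table of class `VariancePartition`: `probe_id`, `VE_<f1>`,
#'   `VE_<f2>`, `VE_residual` (per-site fractions summing to 1), plus the raw
#'   component columns `var_<f1>`, `var_<f2>`, `var_residual`.
#' @export
variance_partition <- function(bm, factors = c("cell_line", "lab"),
                               sample_meta = NULL) {
  if (inherits(bm, "BetaMatrix")) {
    Y <- bm$beta
    meta <- bm$sample_meta
    probe_id <- bm$site_meta$probe_id
  } else {
    Y <- as.matrix(bm)
    meta <- as.data.table(sample_meta)
    .assert(!is.null(meta), "sample_meta required for a bare matrix")
    probe_id <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  }
  .assert(length(factors) == 2L && all(factors %in% names(meta)),
          "factors must name two sample metadata columns")
  f1_all <- as.character(meta[[factors[1]]])
  f2_all <- as.character(meta[[factors[2]]])
  .assert(length(unique(f1_all)) >= 2L && length(unique(f2_all)) >= 2L,
          "each factor needs at least two levels")

  comp <- matrix(NA_real_, nrow(Y), 3L)
  pattern <- apply(is.na(Y), 1L, function(z) paste(which(z), collapse = ","))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    drop_cols <- if (nzchar(pat)) as.integer(strsplit(pat, ",")[[1]]) else integer()
    use <- setdiff(seq_len(ncol(Y)), drop_cols)
    if (length(use) < 4L) next
    f1 <- factor(f1_all[use]); f2 <- factor(f2_all[use])
    if (nlevels(f1) < 2L || nlevels(f2) < 2L) next
    d <- .h3_design(f1, f2)
    Ysub <- Y[rows, use, drop = FALSE]
    qf <- function(Q) rowSums((Ysub %*% Q) * Ysub)
    s_e <- qf(d$M) / d$df_e
    s_a <- pmax(0, (qf(d$Qa) - s_e * d$df_a) / d$c_a)
    s_b <- pmax(0, (qf(d$Qb) - s_e * d$df_b) / d$c_b)
    comp[rows, ] <- cbind(s_a, s_b, s_e)
  }
  tot <- rowSums(comp)
  ve <- comp / ifelse(is.na(tot) | tot > 0, tot, 1)
  zero <- which(!is.na(tot) & tot == 0)
  if (length(zero)) ve[zero, ] <- rep(c(0, 0, 1), each = length(zero))
  out <- data.table(probe_id = probe_id,
                    v1 = ve[, 1], v2 = ve[, 2], v3 = ve[, 3],
                    c1 = comp[, 1], c2 = comp[, 2], c3 = comp[, 3])
  setnames(out, c("v1", "v2", "v3", "c1", "c2", "c3"),
           c(paste0("VE_", factors), "VE_residual",
             paste0("var_", factors), "var_residual"))
  setattr(out, "class", c("VariancePartition", class(out)))
  out[]
}

#' Rank normalization pipelines by median variance explained by cell line
#'
#' Runs [variance_partition()] on each (externally normalized) matrix and
#' ranks pipelines by the median per-site fraction of variance explained by
#' cell line, descending.  A better normalization removes technical (lab)
#' variation and leaves biological (cell-line) differences.
#'
#' @param matrices named list of BetaMatrix objects sharing sites/samples.
#' @param factors forwarded to [variance_partition()].
#' @return list: `ranking` (data.table pipeline/median_VE_cellline/rank) and
#'   `distributions` (named list of per-site VE vectors).
#' @export
pipeline_rank <- function(matrices, factors = c("cell_line", "lab")) {
  .assert(length(matrices) >= 1L, "no matrices supplied")
  nm <- names(matrices) %||% paste0("pipeline", seq_along(matrices))
  ve_col <- paste0("VE_", factors[1])
  dists <- lapply(matrices, function(m)
    variance_partition(m, factors = factors)[[ve_col]])
  names(dists) <- nm
  ranking <- data.table(pipeline = nm,
                        median_VE_cellline = vapply(dists, median, 0,
                                                    na.rm = TRUE))
  setorder(ranking, -median_VE_cellline)
  ranking[, rank := .I]
  list(ranking = ranking[], distributions = dists)
}

#' Genotype cluster calls at SNP probes
#'
#' Naive thresholding of each sample's beta at each SNP probe, within each
#' lab: beta < 0.25 is cluster 1 (homozygous), beta > 0.75 is cluster 3
#' (other homozygote), and the middle band is cluster 2 (heterozygous).  The
#' `"span"` rule (default) treats \[0.25, 0.75\] as cluster 2; the
#' `"literal"` rule uses \[0.25, 0.50\] and leaves (0.50, 0.75\] unassigned
#' (NA).
#'
#' @param bm BetaMatrix with flagged SNP probes.
#' @param rule `"span"` or `"literal"`.
#' @return data.table: `probe_id`, `sample_id`, `lab`, `beta`, `cluster`.
#' @export
snp_genotype_clusters <- function(bm, rule = c("span", "literal")) {
  stopifnot(inherits(bm, "BetaMatrix"))
  rule <- match.arg(rule)
  snp <- which(bm$site_meta$is_snp_probe)
  .assert(length(snp) > 0L, "no SNP probes flagged in the matrix")
  long <- data.table(
    probe_id = rep(bm$site_meta$probe_id[snp], ncol(bm$beta)),
    sample_id = rep(bm$sample_meta$sample_id, each = length(snp)),
    lab = rep(bm$sample_meta$lab, each = length(snp)),
    beta = as.numeric(bm$beta[snp, , drop = FALSE]))
  hi2 <- if (rule == "span") 0.75 else 0.50
  long[, cluster := fifelse(beta < 0.25, 1L,
                     fifelse(beta <= hi2, 2L,
                      fifelse(beta > 0.75, 3L, NA_integer_)))]
  long[]
}

#' Technical-noise variance threshold from SNP-probe genotype clusters
#'
#' Because SNP probes report genotype, all samples in one genotype cluster
#' should read identically; their within-cluster variance measures pure
#' technical noise.  Within each lab, the beta variance of every
#' (probe, cluster) group with at least two samples is computed, and the
#' threshold is the 95th percentile of the pooled variances (linear
#' interpolation between order statistics).  Set `per_lab = TRUE` for one
#' threshold per lab instead of pooling.
#'
#' @param bm BetaMatrix.
#' @param probs percentile (default 0.95).
#' @param rule genotype rule forwarded to [snp_genotype_clusters()].
#' @param per_lab compute thresholds per lab rather than pooled.
#' @return list: `threshold` (scalar, or named vector when `per_lab`),
#'   `variances` (data.table lab/probe_id/cluster/n/variance).
#' @export
technical_variance_threshold <- function(bm, probs = 0.95,
                                         rule = c("span", "literal"),
                                         per_lab = FALSE) {
  cl <- snp_genotype_clusters(bm, rule = match.arg(rule))
  v <- cl[!is.na(cluster),
          .(n = .N, variance = var(beta)),
          by = .(lab, probe_id, cluster)][n >= 2L]
  .assert(nrow(v) > 0L, "no genotype cluster has >= 2 samples")
  threshold <- if (per_lab) {
    vapply(split(v$variance, v$lab), .pctl, 0, probs = probs)
  } else .pctl(v$variance, probs)
  list(threshold = threshold, variances = v[])
}

#' Classify sites as low- or high-varying
#'
#' A site is low-varying iff its across-sample beta variance is strictly
#' below the technical-noise threshold (variance exactly at the threshold is
#' high-varying).
#'
#' @param bm BetaMatrix.
#' @param threshold scalar variance threshold (>= 0), e.g. from
#'   [technical_variance_threshold()].
#' @return data.table: `probe_id`, `variance`, `label` ("low"/"high").
#' @export
classify_low_varying <- function(bm, threshold) {
  stopifnot(inherits(bm, "BetaMatrix"))
  .assert(is.numeric(threshold) && length(threshold) == 1L && threshold >= 0,
          "threshold must be a single non-negative number")
  v <- apply(bm$beta, 1L, var, na.rm = TRUE)
  data.table(probe_id = bm$site_meta$probe_id, variance = v,
             label = fifelse(v < threshold, "low", "high"))
}
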