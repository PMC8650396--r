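test_that("site_filter applies the >=min_cov in >=min_samples rule", {
  mk_grp <- function(covs, starts = c(0L, 2L)) {
    lapply(covs, function(cv)
      mk_callset("chr1", starts[seq_along(cv)], cv, 0L))
  }
  # per-sample coverages at one site: group1 {6,4,5}, group2 {5,5,0->absent}
  g1 <- list(mk_callset("chr1", 0L, 6L, 0L), mk_callset("chr1", 0L, 4L, 0L),
             mk_callset("chr1", 0L, 5L, 0L))
  g2 <- list(mk_callset("chr1", 0L, 5L, 0L), mk_callset("chr1", 0L, 5L, 0L),
             mk_callset("chr1", 2L, 1L, 0L))
  keep <- site_filter(g1, g2)
  expect_equal(keep$start, 0L)           # 2 of 3 qualify in each group
  # one group all below 5x -> fail
  g2b <- list(mk_callset("chr1", 0L, 4L, 0L), mk_callset("chr1", 0L, 4L, 0L),
              mk_callset("chr1", 0L, 4L, 0L))
  expect_equal(nrow(site_filter(g1, g2b)), 0L)
  expect_error(site_filter(g1[1], g2), "min_samples")
})

test_that("site_filter equals a brute-force rule oracle", {
  tr <- small_truth(seed = 81L, n_sites = 500L)
  g1 <- lapply(paste0("A", 1:3), function(g) {
    cs <- generate_callset(tr, "TruSeq", g)
    thin_counts(cs, 7, seed = 1L)   # low coverage so the filter bites
  })
  g2 <- lapply(paste0("B", 1:3), function(g)
    thin_counts(generate_callset(tr, "TruSeq", g), 7, seed = 2L))
  keep <- site_filter(g1, g2, min_cov = 5L, min_samples = 2L)
  all_sites <- unique(data.table::rbindlist(
    lapply(c(g1, g2), function(x) x$records[, .(chrom, start)])))
  ok <- vapply(seq_len(nrow(all_sites)), function(i) {
    cnt <- function(grp) sum(vapply(grp, function(x) {
      r <- x$records[chrom == all_sites$chrom[i] & start == all_sites$start[i]]
      nrow(r) == 1L && r$n_meth + r$n_unmeth >= 5L
    }, TRUE))
    cnt(g1) >= 2L && cnt(g2) >= 2L
  }, TRUE)
  oracle <- all_sites[ok][order(chrom, start)]
  expect_equal(keep, oracle, ignore_attr = TRUE)
})

test_that("fit_site matches stats::glm deviance and p to 1e-6 relative", {
  set.seed(91)
  worst <- 0
  for (i in 1:100) {
    cov <- sample(5:60, 6L, TRUE)
    p <- runif(6, 0.2, 0.8)
    m <- rbinom(6L, cov, p); u <- cov - m
    g <- rep(c("A", "B"), each = 3L)
    got <- fit_site(m, u, g)
    fit <- suppressWarnings(glm(cbind(m, u) ~ g, family = binomial()))
    stat_ref <- fit$null.deviance - fit$deviance
    p_ref <- pchisq(stat_ref, 1, lower.tail = FALSE)
    worst <- max(worst, abs(got$stat - stat_ref) / max(stat_ref, 1e-8),
                 abs(got$p - p_ref) / max(p_ref, 1e-8))
  }
  expect_lt(worst, 1e-6)
})

test_that("fit_site degenerate inputs: no effect and separation", {
  # identical group counts -> statistic 0, p = 1
  out <- fit_site(c(5L, 5L, 5L, 5L), c(5L, 5L, 5L, 5L), rep(c("A", "B"), each = 2))
  expect_equal(out$stat, 0)
  expect_equal(out$p, 1)
  # all-zero in both groups -> statistic 0
  z <- fit_site(rep(0L, 4), rep(10L, 4), rep(c("A", "B"), each = 2))
  expect_equal(z$stat, 0)
  # complete separation stays finite and extreme
  sep <- fit_site(c(100L, 100L, 100L, 0L, 0L, 0L),
                  c(0L, 0L, 0L, 100L, 100L, 100L),
                  rep(c("A", "B"), each = 3))
  expect_true(is.finite(sep$stat))
  expect_lt(sep$p, 1e-10)
  # strong planted effect
  big <- fit_site(c(90L, 90L, 90L, 10L, 10L, 10L),
                  c(10L, 10L, 10L, 90L, 90L, 90L),
                  rep(c("A", "B"), each = 3))
  expect_lt(big$p, 1e-10)
})

test_that("bh_adjust equals the hand-computed step-up and p.adjust", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.013), 0.013)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(101)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    # independent step-up oracle: explicit min over j >= i
    o <- order(p); ps <- p[o]; m <- length(p)
    q_oracle <- numeric(m)
    for (j in seq_len(m))
      q_oracle[o[j]] <- min(1, min(m / seq(j, m) * ps[seq(j, m)]))
    expect_equal(q, q_oracle)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p))
  }
})

test_that("pmd is the difference of group-pooled proportions", {
  g <- rep(c("A", "B"), each = 2)
  expect_equal(pmd(c(40L, 40L), c(10L, 10L), g[c(1, 3)]), 0.8 - 0.8)
  # pooled 0.80 vs 0.55 -> 0.25
  out <- pmd(c(40L, 40L, 33L, 22L), c(10L, 10L, 27L, 18L), g)
  expect_equal(out, 0.8 - 0.55)
  set.seed(111)
  for (i in 1:10) {
    m <- sample(0:50, 6, TRUE); u <- sample(1:50, 6, TRUE)
    gg <- rep(c("A", "B"), each = 3)
    hand <- sum(m[1:3]) / sum(m[1:3] + u[1:3]) - sum(m[4:6]) / sum(m[4:6] + u[4:6])
    expect_equal(pmd(m, u, gg), hand)
  }
})

test_that("dm_test recovers planted differential sites with BH control", {
  cfg <- sim_config(seed = 121L, n_sites = 4000L,
                    chrom_layout = c(chr1 = 1000000L), spike_in = list(),
                    dm_fraction = 0.05, dm_pmd = 0.4)
  tr <- generate_truth(cfg)
  g1 <- lapply(paste0("A", 1:3), function(g)
    thin_counts(generate_callset(tr, "EMSeq", g), 20, seed = 1L))
  g2 <- lapply(paste0("B", 1:3), function(g)
    thin_counts(generate_callset(tr, "EMSeq", g), 20, seed = 2L))
  res <- dm_test(g1, g2)
  expect_s3_class(res, "DMResult")
  expect_true(all(res$q >= res$p))
  expect_true(all(res$pmd >= -1 & res$pmd <= 1))
  truth_dm <- tr$sites[dm == TRUE, .(chrom, start)]
  called <- res[significant == TRUE, .(chrom, start)]
  tp <- nrow(merge(called, truth_dm, by = c("chrom", "start")))
  expect_gt(tp / nrow(truth_dm), 0.8)                 # power at PMD 0.4
  expect_lt((nrow(called) - tp) / max(nrow(called), 1), 0.1)
})

test_that("concordance metrics match their definitions on toy sets", {
  universe <- as.character(1:10)
  dma <- list(A = c("1", "2", "3", "4"), B = c("1", "2"), C = c("1", "2"),
              D = c("1", "5"), E = c("1"), F = character())
  rep_ <- concordance(dma, universe, k = 4L)
  pa <- rep_$per_assay
  # site "1" is called by 5 assays, "2" by 3 -> DM4+ = {"1"}
  expect_equal(unname(rep_$dmk_sizes["DM4+"]), 1L)
  A <- pa[assay == "A"]
  expect_equal(A$unique_fraction, 2 / 4)   # sites 3,4 unique to A
  expect_equal(A$specificity, 1 / 4)
  expect_equal(A$sensitivity, 1)
  # assay disjoint from all others
  dma2 <- list(A = c("1", "2"), B = c("1", "2"), C = c("1", "2"),
               D = c("1", "2"), X = c("9", "10"))
  r2 <- concordance(dma2, universe, k = 4L)
  X <- r2$per_assay[assay == "X"]
  expect_equal(X$unique_fraction, 1)
  expect_equal(X$specificity, 0)
  # DM(k+1)+ subset of DMk+
  expect_true(all(diff(unname(r2$dmk_sizes)) <= 0))
  expect_error(concordance(dma, character()), "universe")
})

test_that("concordance and agreement_by_coverage equal brute force on random configs", {
  set.seed(131)
  for (trial in 1:20) {
    universe <- as.character(1:40)
    dma <- lapply(1:6, function(i) sample(universe, sample(0:25, 1)))
    names(dma) <- paste0("a", 1:6)
    rep_ <- concordance(dma, universe, k = 4L)
    n_calls <- vapply(universe, function(s)
      sum(vapply(dma, function(d) s %in% d, TRUE)), 0L)
    dm4 <- universe[n_calls >= 4L]
    for (i in 1:6) {
      s <- dma[[i]]
      row <- rep_$per_assay[assay == paste0("a", i)]
      if (length(s)) {
        expect_equal(row$unique_fraction, mean(n_calls[s] == 1L))
        expect_equal(row$specificity, mean(s %in% dm4))
        expect_equal(row$specificity_other,
                     mean((n_calls[s] - 1L) >= 3L))
      }
      if (length(dm4)) expect_equal(row$sensitivity, mean(dm4 %in% s))
    }
    for (j in 1:6)
      expect_equal(unname(rep_$dmk_sizes[j]), sum(n_calls >= j))
  }
  # agreement-by-coverage table vs brute-force tabulation
  set.seed(132)
  universe <- as.character(1:200)
  dma <- lapply(1:6, function(i) sample(universe, 80))
  names(dma) <- paste0("a", 1:6)
  med_cov <- setNames(runif(200, 5, 60), universe)
  abc <- agreement_by_coverage(dma, med_cov, n_bins = 5L)
  n_calls <- vapply(universe, function(s)
    sum(vapply(dma, function(d) s %in% d, TRUE)), 0L)
  for (i in 1:6) {
    s <- dma[[i]]
    cv <- med_cov[s]
    lo <- quantile(cv, 0.05, type = 7); hi <- quantile(cv, 0.95, type = 7)
    expect_equal(abc[[i]]$bounds, unname(c(lo, hi)), ignore_attr = TRUE)
    keep <- s[cv >= lo & cv <= hi]
    expect_equal(sum(abc[[i]]$table), length(keep))
    # row margins: number of assays agreeing
    rows <- rowSums(abc[[i]]$table)
    for (k in 1:6)
      expect_equal(unname(rows[k]), sum(n_calls[keep] == k))
  }
})

test_that("array_pmd equals genome-mean arithmetic and a mixed-model oracle", {
  cfg <- array_config(seed = 141L, var_cellline = 0.02, var_lab = 0.001,
                      var_residual = 0.004, n_sites = 40L)
  bm <- drop_snp(generate_array(cfg))
  apmd <- array_pmd(bm, paste0("A", 1:3), paste0("B", 1:3))
  # hand oracle: genome means then group means
  hand <- vapply(seq_len(nrow(bm$beta)), function(i) {
    gm <- vapply(c(paste0("A", 1:3), paste0("B", 1:3)), function(cl)
      mean(bm$beta[i, bm$sample_meta$cell_line == cl]), 0)
    mean(gm[1:3]) - mean(gm[4:6])
  }, 0)
  expect_equal(unname(apmd), hand)
  # balanced design: equals the lme4 random-intercept group effect
  skip_if_not_installed("lme4")
  keep <- bm$sample_meta$cell_line != "C7"
  meta <- bm$sample_meta[keep]
  grp <- factor(ifelse(substr(meta$cell_line, 1, 1) == "A", "g1", "g2"),
                levels = c("g2", "g1"))
  for (i in 1:5) {
    df <- data.frame(y = bm$beta[i, keep], genome = meta$cell_line, grp = grp)
    fit <- lme4::lmer(y ~ grp + (1 | genome), data = df,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    expect_equal(unname(apmd[i]), unname(lme4::fixef(fit)["grpg1"]),
                 tolerance = 1e-6)
  }
})

test_that("array_pmd weights genomes equally despite unequal replicates", {
  # 2 genomes per group; genome A1 has 3 replicates, others 1
  beta <- matrix(c(0.9, 0.9, 0.9, 0.7, 0.5, 0.3), nrow = 1)
  sm <- data.table(sample_id = paste0("s", 1:6),
                   cell_line = c("A1", "A1", "A1", "A2", "B1", "B2"),
                   lab = "L1", replicate = c(1:3, 1, 1, 1), assay = "array")
  bm <- beta_matrix(beta, data.table(probe_id = "p1", is_snp_probe = FALSE), sm)
  out <- array_pmd(bm, c("A1", "A2"), c("B1", "B2"))
  expect_equal(unname(out), (0.9 + 0.7) / 2 - (0.5 + 0.3) / 2)
  expect_warning(array_pmd(bm, c("A1", "A2", "A9"), c("B1", "B2")), "omitted")
})

test_that("array_seq_dm_agreement counts threshold crossings both ways", {
  apmd <- setNames(c(0.5, 0.25, 0.1, -0.3, 0), paste0("p", 1:5))
  dma <- list(x = c("p1", "p3"), y = c("p2", "p4"), z = character())
  got <- array_seq_dm_agreement(dma, apmd, threshold = 0.2)
  expect_equal(got[assay == "x"]$frac_dma_with_array_pmd, 0.5)
  expect_equal(got[assay == "y"]$frac_dma_with_array_pmd, 1)
  expect_true(is.na(got[assay == "z"]$frac_dma_with_array_pmd))
  # reverse direction: |PMD|>=0.2 sites are p1,p2,p4
  expect_equal(got[assay == "x"]$frac_array_pmd_in_dma, 1 / 3)
  # threshold 0 -> every site counts
  all_in <- array_seq_dm_agreement(list(x = c("p1", "p5")), apmd, threshold = 0)
  expect_equal(all_in$frac_dma_with_array_pmd, 1)
})
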