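test_that("sim_config validates its invariants", {
  expect_error(sim_config(meth_mixture = list(weights = c(0.5, 0.5, 0.5),
                                              shapes = list(c(1, 1), c(1, 1), c(1, 1)))),
               "summing to 1")
  expect_error(sim_config(dm_pmd = 1.2), "dm_pmd")
  cfg <- sim_config()
  expect_s3_class(cfg, "SimConfig")
  expect_equal(cfg$n_genomes_per_group, 3L)
})

test_that("generate_truth is deterministic and respects dm_fraction", {
  cfg <- sim_config(seed = 4L, n_sites = 2000L)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$sites, t2$sites)

  none <- generate_truth(sim_config(seed = 4L, n_sites = 500L, dm_fraction = 0))
  expect_true(all(none$sites$p_A == none$sites$p_B))
  expect_false(any(none$sites$dm))

  some <- generate_truth(sim_config(seed = 1L, n_sites = 10000L,
                                    dm_fraction = 0.1, dm_pmd = 0.3))
  n_dm <- sum(some$sites$dm)
  n_main <- sum(!some$sites$spike)
  expect_gt(n_dm, 0.1 * n_main - 4 * sqrt(0.1 * 0.9 * n_main))
  expect_lt(n_dm, 0.1 * n_main + 4 * sqrt(0.1 * 0.9 * n_main))
  dm <- some$sites[dm == TRUE]
  expect_equal(abs(dm$p_A - dm$p_B), rep(0.3, nrow(dm)))
  nd <- some$sites[dm == FALSE]
  expect_true(all(nd$p_A == nd$p_B))
})

test_that("spike-in contigs carry fixed truth", {
  tr <- small_truth()
  lam <- tr$sites[chrom == "lambda"]
  puc <- tr$sites[chrom == "pUC19"]
  expect_true(all(lam$p_A == 0) && all(lam$spike))
  expect_true(all(puc$p_A == 1))
})

test_that("generate_callset honours truth, conversion error and dispersion", {
  cfg <- sim_config(seed = 2L, n_sites = 1000L, conversion_error = 0,
                    chrom_layout = c(chr1 = 500000L))
  tr <- generate_truth(cfg)
  cs <- generate_callset(tr, "EMSeq", "A1")
  # fully methylated spike-in: no unmethylated observations when error = 0
  expect_true(all(cs$records[chrom == "pUC19"]$n_unmeth == 0L))
  expect_true(all(cs$records[chrom == "lambda"]$n_meth == 0L))
  expect_error(generate_callset(tr, "NotAnAssay", "A1"), "unknown assay")
  expect_error(generate_callset(tr, "EMSeq", "Z9"), "unknown genome")
  # determinism
  expect_identical(generate_callset(tr, "EMSeq", "A1")$records, cs$records)
})

test_that("callset coverage matches the profile mean and dispersion model", {
  cfg <- sim_config(seed = 6L, n_sites = 100000L,
                    chrom_layout = c(chr1 = 20000000L),
                    spike_in = list(),
                    assay_profiles = list(
                      even = list(mean_cov = 20, dispersion = "poisson",
                                  nb_size = NA, island_mult = 1),
                      heavy = list(mean_cov = 20, dispersion = "nb",
                                   nb_size = 1, island_mult = 1)))
  tr <- generate_truth(cfg)
  even <- generate_callset(tr, "even", "A1")
  heavy <- generate_callset(tr, "heavy", "A1")
  # law of large numbers: mean within 2% of the profile (covered sites only;
  # at 20x the zero-truncation effect is negligible)
  expect_lt(abs(mean(coverage_of(even)) - 20) / 20, 0.02)
  # heavy-tailed profile strictly more dispersed at the same mean
  expect_gt(var(as.numeric(coverage_of(heavy))),
            var(as.numeric(coverage_of(even))))
})

test_that("generate_reads aggregation reproduces the call set exactly", {
  tr <- small_truth(seed = 8L, n_sites = 800L)
  cs <- generate_callset(tr, "TruSeq", "B2")
  for (mspr in c(1, 5)) {
    rs <- generate_reads(cs, mean_sites_per_read = mspr, seed = 3L)
    agg <- aggregate_reads(rs)
    expect_identical(agg$records[, .(chrom, start, n_meth, n_unmeth)],
                     cs$records[, .(chrom, start, n_meth, n_unmeth)])
  }
  expect_error(generate_reads(cs, mean_sites_per_read = 0.5), ">= 1")
})

test_that("reads are contiguous site runs with roughly the requested length", {
  tr <- generate_truth(sim_config(seed = 10L, n_sites = 10000L,
                                  chrom_layout = c(chr1 = 2000000L),
                                  spike_in = list()))
  cs <- generate_callset(tr, "EMSeq", "A1")
  rs <- generate_reads(cs, mean_sites_per_read = 5, seed = 1L)
  sizes <- rs$obs[, .N, by = read_id]$N
  expect_lt(abs(mean(sizes) - 5) / 5, 0.1)
  # contiguity: within a read, covered starts are consecutive call-set sites
  site_rank <- seq_len(n_sites(cs))
  names(site_rank) <- as.character(cs$records$start)
  gaps <- rs$obs[, .(ok = all(diff(site_rank[as.character(start)]) == 1L)),
                 by = read_id]
  expect_true(all(gaps$ok))
  # single-site reads when mean_sites_per_read = 1... is not required
  # (geometric draw), but aggregation identity held above
})

test_that("generate_array emits the documented layout and SNP probes", {
  cfg <- sim_config(seed = 3L, n_sites = 100L)
  bm <- generate_array(cfg)
  expect_equal(sum(bm$site_meta$is_snp_probe), 59L)
  expect_equal(ncol(bm$beta), 28L)  # 7 cell lines x (2+1+1) replicates
  expect_true(all(bm$beta >= 0 & bm$beta <= 1))
  # determinism
  expect_identical(generate_array(cfg)$beta, bm$beta)
})

test_that("zero variance components give identical replicates per cell line", {
  cfg <- array_config(seed = 2L, var_cellline = 0.04, var_lab = 0,
                      var_residual = 0, n_sites = 50L)
  bm <- generate_array(cfg)
  reg <- !bm$site_meta$is_snp_probe
  for (cl in unique(bm$sample_meta$cell_line)) {
    cols <- which(bm$sample_meta$cell_line == cl)
    spread <- apply(bm$beta[reg, cols, drop = FALSE], 1L, function(z)
      max(z) - min(z))
    expect_equal(max(spread), 0)
  }
})

test_that("SNP probes respect trio structure (child shares parental alleles)", {
  cfg <- sim_config(seed = 9L, n_sites = 100L)
  bm <- generate_array(cfg)
  snp <- bm$site_meta$is_snp_probe
  one_col <- function(cl) {
    i <- which(bm$sample_meta$cell_line == cl)[1]
    g <- round((bm$beta[snp, i] - 0.05) / 0.45)  # back to genotype 0/1/2
    pmin(pmax(g, 0), 2)
  }
  child <- one_col("A1"); father <- one_col("A2"); mother <- one_col("A3")
  # Mendelian consistency: child genotype must be attainable from parents
  ok <- mapply(function(ch, f, m) {
    fa <- unique(c(floor(f / 2), ceiling(f / 2)))
    ma <- unique(c(floor(m / 2), ceiling(m / 2)))
    ch %in% outer(fa, ma, `+`)
  }, child, father, mother)
  expect_true(all(ok))
})

test_that("planted array variance components are recovered", {
  cfg <- array_config(seed = 21L, var_cellline = 0.09, var_lab = 0,
                      var_residual = 0.01, n_sites = 2000L)
  vp <- variance_partition(drop_snp(generate_array(cfg)))
  expect_lt(abs(median(vp$VE_cell_line) - 0.9), 0.05)
})

test_that("annotations follow the island/shore/shelf and promoter definitions", {
  cfg <- sim_config(n_sites = 100L, chrom_layout = c(chr1 = 400000L))
  an <- generate_annotations(cfg)
  expect_s3_class(an, "AnnotationSet")
  # TSS at 50000, + strand: promoter [49000, 50000)
  g1 <- an$genes[1]
  expect_equal(g1$tss, 50000L)
  prom <- an$features[label == "promoter" & start < g1$tss & end == g1$tss]
  expect_equal(prom$start, g1$tss - 1000L)
  # shores are the 2 kb flanks, shelves the next 2 kb; all three disjoint
  isl <- an$islands[1]
  expect_true(any(an$shores$start == isl$start - 2000L))
  expect_true(any(an$shelves$start == isl$start - 4000L))
  lab_iv <- rbind(an$islands[, .(start, end, lab = "i")],
                  an$shores[, .(start, end, lab = "sh")],
                  an$shelves[, .(start, end, lab = "sf")])
  bases <- unlist(Map(seq, lab_iv$start, lab_iv$end - 1L))
  expect_false(anyDuplicated(bases) > 0)
  # deterministic: same config, same annotations
  expect_identical(generate_annotations(cfg)$features, an$features)
})

test_that("shore/shelf arithmetic matches the definitional example", {
  # island [10000,10500) => shore [8000,10000)+[10500,12500),
  #                         shelf [6000,8000)+[12500,14500)
  isl <- data.table(chrom = "c", start = 10000L, end = 10500L)
  sh <- methylbench:::.flank_minus(isl, 2000L, exclude = isl)
  sf <- methylbench:::.flank_minus(isl, 4000L,
                                   exclude = methylbench:::.merge_intervals(rbind(isl, sh)))
  expect_equal(sh[order(start)],
               data.table(chrom = "c", start = c(8000L, 10500L),
                          end = c(10000L, 12500L)))
  expect_equal(sf[order(start)],
               data.table(chrom = "c", start = c(6000L, 12500L),
                          end = c(8000L, 14500L)))
})

test_that("file emission round-trips: bedGraph, beta CSV, FASTA, BED", {
  dir <- withr::local_tempdir()
  tr <- small_truth(seed = 12L, n_sites = 300L, chrom_layout = c(chr1 = 200000L))
  cs <- generate_callset(tr, "EMSeq", "A1")
  p <- file.path(dir, "x.bedGraph")
  write_bedgraph(cs, p)
  expect_identical(read_bedgraph(p)$records[, .(chrom, start, n_meth)],
                   cs$records[, .(chrom, start, n_meth)])
  bm <- generate_array(tr$config)
  write_beta_csv(bm, file.path(dir, "b.csv"), file.path(dir, "s.csv"))
  back <- read_beta_csv(file.path(dir, "b.csv"), file.path(dir, "s.csv"))
  expect_equal(back$beta, bm$beta, tolerance = 1e-12)
  expect_equal(back$sample_meta$cell_line, bm$sample_meta$cell_line)
  fa <- file.path(dir, "ref.fa")
  write_truth_fasta(tr, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_setequal(names(seqs), c("chr1", "lambda", "pUC19"))
  # CG forced at every truth site
  chr1 <- as.character(Biostrings::subseq(
    seqs[["chr1"]], tr$sites[chrom == "chr1"]$start[1] + 1L, width = 2L))
  expect_equal(chr1, "CG")
  beds <- write_annotations_bed(generate_annotations(tr$config),
                                file.path(dir, "annot"))
  expect_true(all(file.exists(beds)))
})
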