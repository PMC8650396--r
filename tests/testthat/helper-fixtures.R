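library(data.table)

# quick hand-built call set from parallel vectors
mk_callset <- function(chrom, start, n_meth, n_unmeth, strand = "*",
                       context = "CpG", ...) {
  w <- if (identical(strand, "*")) 2L else 1L
  methyl_callset(data.table(chrom = chrom, start = as.integer(start),
                            end = as.integer(start) + w, strand = strand,
                            context = context, n_meth = as.integer(n_meth),
                            n_unmeth = as.integer(n_unmeth)), ...)
}

# random single-chromosome call set
rand_callset <- function(n, seed = 1L, max_cov = 50L, chrom = "chr1", ...) {
  set.seed(seed)
  start <- sort(sample.int(n * 20L, n)) * 2L
  cov <- sample.int(max_cov, n, replace = TRUE)
  m <- rbinom(n, cov, runif(n))
  keep <- cov > 0
  mk_callset(chrom, start[keep], m[keep], cov[keep] - m[keep], ...)
}

# small default simulation shared by several files
small_truth <- function(seed = 5L, n_sites = 1500L,
                        chrom_layout = c(chr1 = 500000L), ...) {
  generate_truth(sim_config(seed = seed, n_sites = n_sites,
                            chrom_layout = chrom_layout, ...))
}

# an intermediate-methylation array config for variance-recovery checks:
# mu ~ 0.5 keeps [0,1] clipping negligible so planted components survive
array_config <- function(seed, var_cellline, var_lab, var_residual,
                         n_sites = 500L, reps = c(Lab1 = 2L, Lab2 = 1L, Lab3 = 1L)) {
  sim_config(seed = seed, n_sites = 100L,
             meth_mixture = list(weights = c(0, 1, 0),
                                 shapes = list(c(1, 25), c(50, 50), c(25, 1))),
             array = list(n_sites = as.integer(n_sites),
                          var_cellline = var_cellline, var_lab = var_lab,
                          var_residual = var_residual,
                          n_snp_probes = 59L, snp_noise_sd = 0.015,
                          snp_centers = c(0.05, 0.5, 0.95),
                          reps_per_lab = reps))
}

drop_snp <- function(bm) {
  reg <- which(!bm$site_meta$is_snp_probe)
  beta_matrix(bm$beta[reg, , drop = FALSE], bm$site_meta[reg], bm$sample_meta)
}
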