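# Synthetic methylome generator.
#
# Emulates the statistical structure of a multi-assay methylome benchmarking
# study: bimodal per-CpG methylation, assay-specific coverage dispersion
# (even Poisson-like vs heavy-tailed negative-binomial), island-coverage
# modulation, fully (un)methylated spike-in contigs with a conversion-error
# rate, two family groups of genomes with planted differential sites, and
# array beta matrices with cell-line/lab/residual variance components plus
# tri-cluster SNP probes.  Everything is seeded and deterministic.

#' Simulation configuration
#'
#' Collects every knob of the synthetic methylome world.  Defaults describe a
#' desk-scale version of a six-assay, two-trio benchmarking design: bimodal
#' methylation with a 10% intermediate component, ~30% of CpGs inside
#' islands (hypomethylated, as at real promoters), a 0.5% conversion-error
#' rate, fully unmethylated lambda and fully methylated pUC19 spike-ins, and
#' a 30-sample microarray layout (7 cell lines x 3 labs).
#'
#' @param seed integer master seed; all streams derive from it.
#' @param n_sites number of CpG dinucleotides on the main chromosomes.
#' @param chrom_layout named integer vector of chromosome lengths (bp),
#'   spike-in contigs excluded.
#' @param meth_mixture list with `weights` (unmethylated, intermediate,
#'   methylated; must sum to 1) and `shapes`, a list of three `c(a, b)` beta
#'   parameter pairs for the components.
#' @param island_frac fraction of sites placed inside CpG islands.
#' @param island_unmeth_weight mixture weight of the unmethylated component
#'   for island sites (islands are predominantly unmethylated).
#' @param assay_profiles named list; each element has `mean_cov`,
#'   `dispersion` ("poisson" or "nb"), `nb_size` (NB size parameter, smaller
#'   = heavier tail) and `island_mult` (coverage multiplier inside islands).
#' @param n_genomes_per_group genomes per family group (default 3).
#' @param dm_fraction proportion of sites with a planted group difference.
#' @param dm_pmd planted percent-methylation difference, in \[0,1\].
#' @param conversion_error probability a truly unmethylated cytosine reads as
#'   methylated.
#' @param spike_in named list of spike-in contigs, each with `length` (bp),
#'   `p` (true methylation, 0 or 1) and `n_sites`.
#' @param array list of array-simulation settings: `n_sites`, variance
#'   components `var_cellline`, `var_lab`, `var_residual`, `n_snp_probes`,
#'   `snp_noise_sd`, `snp_centers` (three genotype-cluster centers) and
#'   `reps_per_lab` (replicates of every cell line in each lab).
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 10000L,
                       chrom_layout = c(chr1 = 2000000L),
                       meth_mixture = list(
                         weights = c(0.35, 0.10, 0.55),
                         shapes = list(c(1, 25), c(2, 2), c(25, 1))),
                       island_frac = 0.30,
                       island_unmeth_weight = 0.85,
                       assay_profiles = list(
                         EMSeq      = list(mean_cov = 30, dispersion = "poisson", nb_size = NA, island_mult = 1.0),
                         MethylSeq  = list(mean_cov = 30, dispersion = "poisson", nb_size = NA, island_mult = 1.1),
                         SPLAT      = list(mean_cov = 30, dispersion = "nb", nb_size = 4, island_mult = 1.0),
                         TrueMethyl = list(mean_cov = 30, dispersion = "poisson", nb_size = NA, island_mult = 1.0),
                         TruSeq     = list(mean_cov = 30, dispersion = "nb", nb_size = 0.8, island_mult = 0.6),
                         Nanopore   = list(mean_cov = 30, dispersion = "poisson", nb_size = NA, island_mult = 1.0)),
                       n_genomes_per_group = 3L,
                       dm_fraction = 0.01,
                       dm_pmd = 0.3,
                       conversion_error = 0.005,
                       spike_in = list(
                         lambda = list(length = 48502L, p = 0, n_sites = 2000L),
                         pUC19  = list(length = 2686L,  p = 1, n_sites = 100L)),
                       array = list(
                         n_sites = 2000L,
                         var_cellline = 0.09, var_lab = 0.005, var_residual = 0.01,
                         n_snp_probes = 59L, snp_noise_sd = 0.015,
                         snp_centers = c(0.05, 0.5, 0.95),
                         reps_per_lab = c(Lab1 = 2L, Lab2 = 1L, Lab3 = 1L))) {
  w <- meth_mixture$weights
  .assert(length(w) == 3L && abs(sum(w) - 1) < 1e-8 && all(w >= 0),
          "meth_mixture$weights must be 3 non-negative values summing to 1")
  .assert(dm_pmd >= 0 && dm_pmd <= 1, "dm_pmd must lie in [0,1]")
  .assert(dm_fraction >= 0 && dm_fraction <= 1, "dm_fraction must lie in [0,1]")
  .assert(conversion_error >= 0 && conversion_error < 1,
          "conversion_error must lie in [0,1)")
  .assert(all(unlist(array[c("var_cellline", "var_lab", "var_residual")]) >= 0),
          "array variance components must be >= 0")
  .assert(!is.null(names(chrom_layout)), "chrom_layout must be named")
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 chrom_layout = chrom_layout, meth_mixture = meth_mixture,
                 island_frac = island_frac,
                 island_unmeth_weight = island_unmeth_weight,
                 assay_profiles = assay_profiles,
                 n_genomes_per_group = as.integer(n_genomes_per_group),
                 dm_fraction = dm_fraction, dm_pmd = dm_pmd,
                 conversion_error = conversion_error,
                 spike_in = spike_in, array = array),
            class = "SimConfig")
}

# Deterministic genomic layout (no RNG): island and gene coordinates are a
# pure function of the chromosome lengths, so truth tables and annotations
# always agree.  Genes every 100 kb (alternating strand) with a 1 kb island
# straddling the TSS; one extra intergenic island per gene interval.
.sim_layout <- function(config) {
  islands <- list(); genes <- list()
  for (chrom in names(config$chrom_layout)) {
    len <- config$chrom_layout[[chrom]]
    tss <- seq(50000L, len - 20000L, by = 100000L)
    if (!length(tss)) next
    strand <- rep_len(c("+", "-"), length(tss))
    genes[[chrom]] <- data.table(
      chrom = chrom,
      start = ifelse(strand == "+", tss, tss - 10000L),
      end = ifelse(strand == "+", tss + 10000L, tss),
      strand = strand, tss = tss,
      gene_id = sprintf("%s_g%d", chrom, seq_along(tss)))
    isl <- rbind(
      data.table(chrom = chrom, start = tss - 500L, end = tss + 500L),
      data.table(chrom = chrom, start = tss + 40000L, end = tss + 41000L))
    islands[[chrom]] <- isl[start >= 0 & end <= len]
  }
  list(islands = if (length(islands)) rbindlist(islands) else
         data.table(chrom = character(), start = integer(), end = integer()),
       genes = if (length(genes)) rbindlist(genes) else
         data.table(chrom = character(), start = integer(), end = integer(),
                    strand = character(), tss = integer(), gene_id = character()))
}

.draw_mixture <- function(n, mixture, unmeth_weight = NULL) {
  w <- mixture$weights
  if (!is.null(unmeth_weight)) {
    # reweight toward the unmethylated component, preserving the relative
    # split of the other two
    rest <- w[2:3] / sum(w[2:3]) * (1 - unmeth_weight)
    w <- c(unmeth_weight, rest)
  }
  comp <- sample.int(3L, n, replace = TRUE, prob = w)
  p <- numeric(n)
  for (k in 1:3) {
    idx <- comp == k
    if (any(idx)) p[idx] <- rbeta(sum(idx), mixture$shapes[[k]][1],
                                  mixture$shapes[[k]][2])
  }
  p
}

#' Generate the ground-truth site table
#'
#' Places CpG dinucleotides on the configured chromosomes (island sites are
#' placed inside the deterministic island layout and drawn from an
#' unmethylation-enriched mixture), plants differential sites between the two
#' genome groups at exactly `dm_pmd`, and appends spike-in contig sites with
#' fixed true methylation.
#'
#' Within a group every genome shares the site's true proportion, so group
#' means at planted sites differ by exactly `dm_pmd` (direction chosen at
#' random among those feasible within \[0,1\]).
#'
#' @param config [sim_config()].
#' @return object of class `SimTruth`: list with `sites` (data.table: chrom,
#'   start, end, island, spike, dm, p_A, p_B), `genomes` (named list of the
#'   two groups) and the generating `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.substream(config$seed, "truth"))
  layout <- .sim_layout(config)

  n_isl <- round(config$n_sites * config$island_frac)
  n_bg <- config$n_sites - n_isl
  pos <- list()
  if (n_isl > 0 && nrow(layout$islands)) {
    isl <- layout$islands[sample.int(nrow(layout$islands), n_isl, replace = TRUE)]
    off <- 2L * as.integer(floor(runif(n_isl) *
                                   pmax(1L, (isl$end - isl$start) %/% 2L - 1L)))
    pos$island <- data.table(chrom = isl$chrom, start = isl$start + off,
                             island = TRUE)
  }
  if (n_bg > 0) {
    chroms <- sample(names(config$chrom_layout), n_bg, replace = TRUE,
                     prob = as.numeric(config$chrom_layout))
    lens <- config$chrom_layout[chroms]
    pos$bg <- data.table(
      chrom = chroms,
      start = 2L * as.integer(floor(runif(n_bg) * (lens / 2 - 2))),
      island = FALSE)
  }
  sites <- unique(rbindlist(pos), by = c("chrom", "start"))
  # re-derive island membership after dedup (background draws may land inside
  # an island)
  if (nrow(layout$islands)) {
    isl_dt <- copy(layout$islands)[, `:=`(istart = start, iend = end - 1L)]
    setkey(isl_dt, chrom, istart, iend)
    qry <- copy(sites)[, `:=`(istart = start, iend = start)]
    ov <- foverlaps(qry, isl_dt[, .(chrom, istart, iend)],
                    by.x = c("chrom", "istart", "iend"), which = TRUE)
    hit <- unique(ov[!is.na(yid)]$xid)
    sites$island[hit] <- TRUE
  }
  p <- numeric(nrow(sites))
  p[sites$island] <- .draw_mixture(sum(sites$island), config$meth_mixture,
                                   config$island_unmeth_weight)
  p[!sites$island] <- .draw_mixture(sum(!sites$island), config$meth_mixture)
  sites[, `:=`(end = start + 2L, spike = FALSE, p_A = p, p_B = p, dm = FALSE)]

  if (config$dm_fraction > 0 && nrow(sites)) {
    dm_idx <- which(runif(nrow(sites)) < config$dm_fraction)
    d <- config$dm_pmd
    for (i in dm_idx) {
      pa <- sites$p_A[i]
      up_ok <- pa + d <= 1; dn_ok <- pa - d >= 0
      if (!up_ok && !dn_ok) { pa <- 1 - d; up_ok <- TRUE }
      up <- if (up_ok && dn_ok) runif(1) < 0.5 else up_ok
      sites$p_A[i] <- pa
      sites$p_B[i] <- if (up) pa + d else pa - d
    }
    sites$dm[dm_idx] <- TRUE
  }

  spikes <- rbindlist(lapply(names(config$spike_in), function(nm) {
    sp <- config$spike_in[[nm]]
    ns <- min(sp$n_sites, max(1L, (sp$length - 4L) %/% 2L))
    st <- 2L * sort(sample.int((sp$length - 2L) %/% 2L, ns))
    data.table(chrom = nm, start = st, island = FALSE, end = st + 2L,
               spike = TRUE, p_A = sp$p, p_B = sp$p, dm = FALSE)
  }))
  sites <- rbind(sites, spikes)
  setorder(sites, chrom, start)
  setcolorder(sites, c("chrom", "start", "end", "island", "spike", "dm",
                       "p_A", "p_B"))
  ng <- config$n_genomes_per_group
  structure(list(sites = sites,
                 genomes = list(A = sprintf("A%d", seq_len(ng)),
                                B = sprintf("B%d", seq_len(ng))),
                 config = config),
            class = "SimTruth")
}

#' Simulate one sample's methylation call set from the truth table
#'
#' Coverage is drawn from the assay's dispersion model — Poisson for even
#' assays, negative-binomial for heavy-tailed ones — with island sites scaled
#' by the island multiplier (and the remaining sites rescaled so the overall
#' mean stays at `mean_cov`).  Methylated counts are
#' Binomial(coverage, p'), where p' = p + (1 - p) * conversion_error.
#' Zero-coverage sites are omitted, mirroring bedGraph convention.
#'
#' @param truth [generate_truth()] output.
#' @param assay name of a profile in the config's `assay_profiles`.
#' @param genome genome label, e.g. `"A1"`; group A uses `p_A`, group B `p_B`.
#' @param replicate replicate label (part of the RNG stream).
#' @param lab lab label (metadata only).
#' @param seed optional override of the config seed.
#' @return [methyl_callset()] of merged dinucleotide records (strand `"*"`).
#' @export
generate_callset <- function(truth, assay, genome, replicate = "rep1",
                             lab = "Lab1", seed = NULL) {
  stopifnot(inherits(truth, "SimTruth"))
  config <- truth$config
  prof <- config$assay_profiles[[assay]]
  if (is.null(prof)) stop("unknown assay profile: ", assay)
  .assert(genome %in% unlist(truth$genomes), "unknown genome label")
  set.seed(.substream(seed %||% config$seed, "callset", assay, genome, replicate))

  s <- truth$sites
  p_true <- if (genome %in% truth$genomes$A) s$p_A else s$p_B
  frac_isl <- mean(s$island)
  norm <- 1 / (frac_isl * prof$island_mult + (1 - frac_isl))
  mu <- prof$mean_cov * norm * ifelse(s$island, prof$island_mult, 1)
  cov <- if (identical(prof$dispersion, "nb"))
    rnbinom(nrow(s), mu = mu, size = prof$nb_size)
  else rpois(nrow(s), mu)
  p_obs <- p_true + (1 - p_true) * config$conversion_error
  n_meth <- rbinom(nrow(s), cov, p_obs)
  keep <- cov > 0L
  rec <- data.table(chrom = s$chrom[keep], start = s$start[keep],
                    end = s$end[keep], strand = "*", context = "CpG",
                    n_meth = n_meth[keep],
                    n_unmeth = cov[keep] - n_meth[keep])
  methyl_callset(rec, assay = assay, lab = lab, genome = genome,
                 replicate = replicate, build = "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand a call set into synthetic reads spanning contiguous CpG runs
#'
#' Stand-in for alignment-level (BAM) data: each read covers a contiguous run
#' of CpG sites, and aggregating the reads site-by-site reproduces the call
#' set's counts exactly (a constructive invariant).  Used to contrast
#' read-level with count-level downsampling.
#'
#' Construction: the call set is peeled into coverage "layers"; within each
#' layer, maximal runs of consecutive still-uncovered sites are cut into
#' reads with geometric lengths (mean `mean_sites_per_read`), and each site's
#' methylated observations are distributed uniformly at random over its
#' layers.
#'
#' @param callset MethylCallSet.
#' @param mean_sites_per_read mean number of CpGs per read (>= 1).
#' @param seed RNG seed.
#' @return object of class `ReadSet`: list with `obs` (data.table: read_id,
#'   chrom, start, meth) and `meta` (the call set's metadata).
#' @export
generate_reads <- function(callset, mean_sites_per_read = 5, seed = 1L) {
  .stopifnot_mcs(callset)
  .assert(mean_sites_per_read >= 1, "mean_sites_per_read must be >= 1")
  .assert(nrow(callset$records) > 0L, "call set is empty")
  set.seed(.substream(seed, "reads"))
  r <- callset$records
  cov <- r$n_meth + r$n_unmeth
  n <- nrow(r)
  # per-site random assignment of methylated observations to layers
  obs_site <- rep.int(seq_len(n), cov)
  layer <- sequence(cov)
  u <- runif(length(obs_site))
  dt <- data.table(site = obs_site, layer = layer, u = u,
                   nm = rep.int(r$n_meth, cov))
  dt[, meth := frank(u, ties.method = "first") <= nm[1], by = site]
  setorder(dt, layer, site)
  # cut each (layer, chromosome-contiguous run) into geometric-length reads
  chrom_i <- as.integer(factor(r$chrom, levels = unique(r$chrom)))
  dt[, run_break := c(TRUE, diff(site) != 1L | diff(layer) != 0L |
                        diff(chrom_i[site]) != 0L)]
  # Run breaks truncate reads, so cutting runs at the nominal geometric rate
  # 1/mean would undershoot the requested length.  Sparse coverage layers are
  # dominated by short runs and cannot be lengthened (their reads are the
  # whole runs); the remaining deficit is spread over the dense layers via
  # one shared reduced cut rate, keeping the expected overall sites/read at
  # the requested value with geometrically bounded lengths.
  L <- mean_sites_per_read
  per_layer <- dt[, .(no = .N, nr = sum(run_break)), by = layer]
  sparse <- per_layer[nr / no >= 1 / L]$layer
  rest <- per_layer[!layer %in% sparse]
  target_reads <- nrow(dt) / L
  p_shared <- if (nrow(rest) && sum(rest$no - rest$nr) > 0) {
    min(1, max(0, (target_reads - sum(per_layer[layer %in% sparse]$nr) -
                     sum(rest$nr)) / sum(rest$no - rest$nr)))
  } else 0
  cut_here <- !(dt$layer %in% sparse) & (runif(nrow(dt)) < p_shared)
  new_read <- dt$run_break | cut_here
  new_read[1] <- TRUE
  dt[, read_id := cumsum(new_read)]
  obs <- dt[, .(read_id, chrom = r$chrom[site], start = r$start[site], meth)]
  setorder(obs, read_id)
  structure(list(obs = obs, meta = callset$meta), class = "ReadSet")
}

#' Aggregate a ReadSet back to a call set
#'
#' @param readset ReadSet.
#' @return MethylCallSet with per-site counts summed over reads.
#' @export
aggregate_reads <- function(readset) {
  stopifnot(inherits(readset, "ReadSet"))
  agg <- readset$obs[, .(n_meth = sum(meth), n_unmeth = sum(!meth)),
                     by = .(chrom, start)]
  agg[, `:=`(end = start + 2L, strand = "*", context = "CpG")]
  do.call(methyl_callset, c(list(records = agg), readset$meta))
}

# ---- microarray simulation ---------------------------------------------

#' Construct a BetaMatrix
#'
#' Sites x samples matrix of array beta values plus the metadata the
#' variance-partition harness needs.
#'
#' @param beta numeric matrix, sites x samples, values in \[0,1\] or NA.
#' @param site_meta data.frame with `probe_id` and `is_snp_probe`.
#' @param sample_meta data.frame with `sample_id`, `cell_line`, `lab`,
#'   `replicate` and `assay`.
#' @export
beta_matrix <- function(beta, site_meta, sample_meta) {
  beta <- as.matrix(beta)
  site_meta <- as.data.table(site_meta)
  sample_meta <- as.data.table(sample_meta)
  .assert(nrow(beta) == nrow(site_meta), "site_meta/beta row mismatch")
  .assert(ncol(beta) == nrow(sample_meta), "sample_meta/beta column mismatch")
  .assert(all(c("probe_id", "is_snp_probe") %in% names(site_meta)),
          "site_meta needs probe_id, is_snp_probe")
  .assert(all(c("sample_id", "cell_line", "lab") %in% names(sample_meta)),
          "sample_meta needs sample_id, cell_line, lab")
  ok <- is.na(beta) | (beta >= 0 & beta <= 1)
  .assert(all(ok), "beta values must lie in [0,1] or be NA")
  rownames(beta) <- site_meta$probe_id
  colnames(beta) <- sample_meta$sample_id
  structure(list(beta = beta, site_meta = site_meta,
                 sample_meta = sample_meta), class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d sites (%d SNP probes) x %d samples; %d cell lines, %d labs\n",
              nrow(x$beta), sum(x$site_meta$is_snp_probe), ncol(x$beta),
              length(unique(x$sample_meta$cell_line)),
              length(unique(x$sample_meta$lab))))
  invisible(x)
}

#' Simulate a methylation microarray beta matrix
#'
#' Ordinary probes follow beta = clip(mu_site + b_cellline + b_lab + e, 0, 1)
#' with independent normal effects whose variances are the configured
#' components.  SNP probes instead report genotype: each founder cell line
#' draws two alleles per probe, children of the two trios inherit one allele
#' from each parent, and the resulting genotype maps to one of three cluster
#' centers plus technical noise.
#'
#' The sample layout crosses 7 cell lines (two trios `A1..A3`, `B1..B3`,
#' child listed first, plus unrelated `C7`) with the configured labs and
#' per-lab replicate counts.
#'
#' @param config [sim_config()].
#' @return [beta_matrix()].
#' @export
generate_array <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  arr <- config$array
  set.seed(.substream(config$seed, "array"))
  cell_lines <- c("A1", "A2", "A3", "B1", "B2", "B3", "C7")
  trios <- list(c(child = "A1", father = "A2", mother = "A3"),
                c(child = "B1", father = "B2", mother = "B3"))
  labs <- names(arr$reps_per_lab)
  .assert(!is.null(labs) && all(arr$reps_per_lab >= 0),
          "array$reps_per_lab must be a named non-negative vector")
  samp <- rbindlist(lapply(labs, function(l) {
    k <- arr$reps_per_lab[[l]]
    if (k == 0L) return(NULL)
    CJ(cell_line = cell_lines, replicate = seq_len(k))[
      , .(cell_line, lab = l, replicate)]
  }))
  samp[, sample_id := sprintf("%s_%s_rep%d", cell_line, lab, replicate)]
  samp[, assay := "array"]
  n_samp <- nrow(samp)

  n_reg <- arr$n_sites
  n_snp <- arr$n_snp_probes
  mu <- .draw_mixture(n_reg, config$meth_mixture)
  b_cell <- matrix(rnorm(n_reg * length(cell_lines),
                         sd = sqrt(arr$var_cellline)),
                   n_reg, dimnames = list(NULL, cell_lines))
  b_lab <- matrix(rnorm(n_reg * length(labs), sd = sqrt(arr$var_lab)),
                  n_reg, dimnames = list(NULL, labs))
  eps <- matrix(rnorm(n_reg * n_samp, sd = sqrt(arr$var_residual)), n_reg)
  beta_reg <- mu + b_cell[, samp$cell_line, drop = FALSE] +
    b_lab[, samp$lab, drop = FALSE] + eps
  beta_reg <- pmin(pmax(beta_reg, 0), 1)

  # SNP probes: founder alleles, Mendelian children, 3 genotype clusters
  founders <- c("A2", "A3", "B2", "B3", "C7")
  geno <- matrix(NA_integer_, n_snp, length(cell_lines),
                 dimnames = list(NULL, cell_lines))
  alleles <- list()
  for (f in founders) {
    alleles[[f]] <- matrix(rbinom(n_snp * 2L, 1L, 0.5), n_snp)
    geno[, f] <- rowSums(alleles[[f]])
  }
  for (tr in trios) {
    pick_f <- rbinom(n_snp, 1L, 0.5) + 1L
    pick_m <- rbinom(n_snp, 1L, 0.5) + 1L
    child_a <- alleles[[tr[["father"]]]][cbind(seq_len(n_snp), pick_f)]
    child_b <- alleles[[tr[["mother"]]]][cbind(seq_len(n_snp), pick_m)]
    geno[, tr[["child"]]] <- child_a + child_b
  }
  centers <- arr$snp_centers
  beta_snp <- matrix(centers[geno[, samp$cell_line, drop = FALSE] + 1L], n_snp) +
    rnorm(n_snp * n_samp, sd = arr$snp_noise_sd)
  beta_snp <- pmin(pmax(beta_snp, 0), 1)

  beta <- rbind(beta_reg, beta_snp)
  site_meta <- data.table(
    probe_id = c(sprintf("cg%07d", seq_len(n_reg)),
                 sprintf("rs%07d", seq_len(n_snp))),
    is_snp_probe = rep(c(FALSE, TRUE), c(n_reg, n_snp)))
  beta_matrix(beta, site_meta, samp[, .(sample_id, cell_line, lab, replicate, assay)])
}

# ---- annotations --------------------------------------------------------

#' Generate the synthetic annotation set
#'
#' Deterministic (seed-free) island and gene layout matching
#' [generate_truth()].  Islands are non-overlapping 1 kb regions; shores are
#' their 2 kb flanks and shelves the next 2 kb (both excluding any island
#' bases).  Gene models yield promoter (1 kb upstream of TSS), up5kb (5 kb to
#' 1 kb upstream), exon and intron intervals, strand-aware.  Features running
#' off a chromosome end are clipped with a warning.
#'
#' @param config [sim_config()].
#' @return object of class `AnnotationSet`: list of data.tables `islands`,
#'   `shores`, `shelves`, `genes`, and `features` (chrom, start, end, label).
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  layout <- .sim_layout(config)
  isl <- .merge_intervals(layout$islands)
  shores <- .flank_minus(isl, 2000L, exclude = isl)
  shelves <- .flank_minus(isl, 4000L,
                          exclude = .merge_intervals(rbind(isl, shores)))
  g <- layout$genes
  feats <- list()
  if (nrow(g)) {
    plus <- g$strand == "+"
    feats$promoter <- data.table(
      chrom = g$chrom,
      start = ifelse(plus, g$tss - 1000L, g$tss),
      end = ifelse(plus, g$tss, g$tss + 1000L), label = "promoter")
    feats$up5kb <- data.table(
      chrom = g$chrom,
      start = ifelse(plus, g$tss - 5000L, g$tss + 1000L),
      end = ifelse(plus, g$tss - 1000L, g$tss + 5000L), label = "up5kb")
    # three 500 bp exons at gene start/middle/end; introns in between
    ex_off <- list(c(0L, 500L), c(4750L, 5250L), c(9500L, 10000L))
    in_off <- list(c(500L, 4750L), c(5250L, 9500L))
    body_start <- g$start
    feats$exon <- rbindlist(lapply(ex_off, function(o)
      data.table(chrom = g$chrom, start = body_start + o[1],
                 end = body_start + o[2], label = "exon")))
    feats$intron <- rbindlist(lapply(in_off, function(o)
      data.table(chrom = g$chrom, start = body_start + o[1],
                 end = body_start + o[2], label = "intron")))
  }
  features <- rbindlist(feats)
  if (nrow(features)) {
    lens <- config$chrom_layout[features$chrom]
    clipped <- features$start < 0L | features$end > lens
    if (any(clipped)) {
      warning(sum(clipped), " feature(s) clipped to chromosome bounds")
      features[, start := pmax(start, 0L)]
      features[, end := pmin(end, lens)]
      features <- features[end > start]
    }
  }
  structure(list(islands = isl, shores = shores, shelves = shelves,
                 genes = g, features = features),
            class = "AnnotationSet")
}

# union of possibly-overlapping intervals, per chromosome
.merge_intervals <- function(dt) {
  if (!nrow(dt)) return(data.table(chrom = character(), start = integer(),
                                   end = integer()))
  dt <- copy(as.data.table(dt))[, .(chrom, start, end)]
  setorder(dt, chrom, start)
  dt[, grp := cumsum(c(TRUE, start[-1] > cummax(end[-.N]) |
                         chrom[-1] != chrom[-.N])), ]
  dt[, .(chrom = chrom[1], start = min(start), end = max(end)), by = grp][
    , grp := NULL][]
}

# flanks of width `width` on both sides of each interval, with `exclude`
# intervals subtracted (used for shores/shelves)
.flank_minus <- function(intervals, width, exclude) {
  if (!nrow(intervals)) return(data.table(chrom = character(),
                                          start = integer(), end = integer()))
  fl <- rbind(
    intervals[, .(chrom, start = pmax(start - width, 0L), end = start)],
    intervals[, .(chrom, start = end, end = end + width)])
  fl <- .merge_intervals(fl[end > start])
  .interval_setdiff(fl, exclude)
}

.interval_setdiff <- function(a, b) {
  if (!nrow(a)) return(a)
  if (!nrow(b)) return(a)
  out <- list()
  for (ch in unique(a$chrom)) {
    ia <- IRanges::IRanges(a[chrom == ch]$start + 1L, a[chrom == ch]$end)
    ib_dt <- b[chrom == ch]
    ib <- if (nrow(ib_dt)) IRanges::IRanges(ib_dt$start + 1L, ib_dt$end)
          else IRanges::IRanges()
    d <- IRanges::setdiff(ia, ib)
    if (length(d))
      out[[ch]] <- data.table(chrom = ch, start = IRanges::start(d) - 1L,
                              end = IRanges::end(d))
  }
  if (length(out)) rbindlist(out) else
    data.table(chrom = character(), start = integer(), end = integer())
}

# ---- file emission ------------------------------------------------------

#' Write synthetic reference FASTA
#'
#' Random sequence per configured chromosome and spike-in contig, with `CG`
#' forced at every truth-table CpG position so sequence and call sets agree.
#'
#' @param truth [generate_truth()] output.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_truth_fasta <- function(truth, path) {
  stopifnot(inherits(truth, "SimTruth"))
  config <- truth$config
  set.seed(.substream(config$seed, "fasta"))
  lens <- c(config$chrom_layout,
            setNames(vapply(config$spike_in, `[[`, 0L, "length"),
                     names(config$spike_in)))
  seqs <- lapply(names(lens), function(ch) {
    s <- sample(c("A", "C", "G", "T"), lens[[ch]], replace = TRUE)
    st <- truth$sites[chrom == ch]$start
    s[st + 1L] <- "C"; s[st + 2L] <- "G"
    paste(s, collapse = "")
  })
  names(seqs) <- names(lens)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}

#' Write an AnnotationSet as BED6 files
#'
#' One file per track (`islands.bed`, `shores.bed`, `shelves.bed`,
#' `genes.bed`, `features.bed`) under `dir`.
#'
#' @param annot AnnotationSet.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_annotations_bed <- function(annot, dir) {
  stopifnot(inherits(annot, "AnnotationSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(dt, name, label, strand = ".") {
    p <- file.path(dir, paste0(name, ".bed"))
    if (nrow(dt)) {
      bed <- data.table(dt$chrom, dt$start, dt$end, label, 0L, strand)
      fwrite(bed, p, sep = "\t", col.names = FALSE)
    } else file.create(p)
    p
  }
  paths <- c(paths,
             emit(annot$islands, "islands", "island"),
             emit(annot$shores, "shores", "shore"),
             emit(annot$shelves, "shelves", "shelf"))
  if (nrow(annot$genes)) {
    p <- file.path(dir, "genes.bed")
    fwrite(annot$genes[, .(chrom, start, end, gene_id, 0L, strand)], p,
           sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  if (nrow(annot$features)) {
    p <- file.path(dir, "features.bed")
    fwrite(annot$features[, .(chrom, start, end, label, 0L, ".")], p,
           sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a BetaMatrix as CSV (matrix + sample sheet)
#' @param bm BetaMatrix.
#' @param matrix_path CSV path for the sites x samples matrix (first column
#'   `probe_id`, second `is_snp_probe`).
#' @param samples_path CSV path for the sample sheet.
#' @return invisibly, both paths.
#' @export
write_beta_csv <- function(bm, matrix_path, samples_path) {
  stopifnot(inherits(bm, "BetaMatrix"))
  out <- cbind(bm$site_meta, as.data.table(bm$beta))
  fwrite(out, matrix_path)
  fwrite(bm$sample_meta, samples_path)
  invisible(c(matrix_path, samples_path))
}

#' Read a BetaMatrix written by [write_beta_csv()]
#' @param matrix_path,samples_path the two CSV paths.
#' @return BetaMatrix.
#' @export
read_beta_csv <- function(matrix_path, samples_path) {
  m <- fread(matrix_path)
  s <- fread(samples_path)
  beta_matrix(as.matrix(m[, -(1:2)]), m[, 1:2], s)
}
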