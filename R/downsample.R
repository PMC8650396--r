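# Coverage normalization by count-level binomial thinning, and the
# count-vs-read-level downsampling comparison.

#' Thin a call set to a target mean CpG coverage
#'
#' Computes the keep fraction f = target / current mean (current mean taken
#' over covered sites) and thins each site's methylated and unmethylated
#' counts independently as Binomial(n, f).  Sites reduced to zero coverage
#' are dropped, per bedGraph convention.  If the set is already at or below
#' the target, it is returned unchanged with a warning.
#'
#' Per-site thinning is unbiased for the methylation proportion: conditional
#' on at least one retained observation, E\[beta\] equals the pre-thinning
#' beta up to the small zero-truncation effect at very low coverage.
#'
#' @param callset MethylCallSet.
#' @param target_mean desired mean coverage (> 0).
#' @param seed RNG seed.
#' @return thinned MethylCallSet; attribute `"keep_fraction"` records f.
#' @export
thin_counts <- function(callset, target_mean, seed = 1L) {
  .stopifnot_mcs(callset)
  .assert(target_mean > 0, "target_mean must be positive")
  cur <- mean(coverage_of(callset))
  if (!is.finite(cur) || cur <= target_mean) {
    warning("current mean coverage (", round(cur, 2),
            ") does not exceed target; returning input unchanged")
    attr(callset, "keep_fraction") <- 1
    return(callset)
  }
  f <- target_mean / cur
  set.seed(.substream(seed, "thin_counts"))
  r <- copy(callset$records)
  r[, `:=`(n_meth = rbinom(.N, n_meth, f),
           n_unmeth = rbinom(.N, n_unmeth, f))]
  r <- r[n_meth + n_unmeth > 0L]
  out <- callset
  out$records <- r
  attr(out, "keep_fraction") <- f
  out
}

#' Thin a ReadSet to a target mean CpG coverage
#'
#' The read-level analogue of [thin_counts()] (the BAM-subsampling route):
#' each read is independently retained with probability
#' f = target / current mean, and retained reads are aggregated back to a
#' call set.  Because one read contributes to every CpG it spans, retained
#' coverage is correlated across neighbouring sites, which makes the
#' achieved mean coverage noisier than count-level thinning.
#'
#' @param readset ReadSet from [generate_reads()].
#' @param target_mean desired mean coverage.
#' @param seed RNG seed.
#' @return MethylCallSet aggregated from the retained reads.
#' @export
thin_reads <- function(readset, target_mean, seed = 1L) {
  stopifnot(inherits(readset, "ReadSet"))
  .assert(target_mean > 0, "target_mean must be positive")
  agg <- readset$obs[, .N, by = .(chrom, start)]
  cur <- mean(agg$N)
  if (cur <= target_mean) {
    warning("current mean coverage does not exceed target; returning aggregate")
    return(aggregate_reads(readset))
  }
  f <- target_mean / cur
  set.seed(.substream(seed, "thin_reads"))
  ids <- unique(readset$obs$read_id)
  keep <- ids[runif(length(ids)) < f]
  obs <- readset$obs[read_id %in% keep]
  .assert(nrow(obs) > 0L, "thinning removed every read; lower the target or reseed")
  out <- readset
  out$obs <- obs
  aggregate_reads(out)
}

#' Compare count-level and read-level downsampling
#'
#' Runs both thinning routes `n_trials` times on the same inputs and reports,
#' per trial, the achieved mean coverage and its absolute error from the
#' target, the retained site counts, and summaries of the beta distribution
#' (global mean beta and the fraction of sites with beta exactly 0 or 1).
#'
#' @param callset MethylCallSet (must equal the readset's aggregation).
#' @param readset companion ReadSet.
#' @param target_mean target mean coverage.
#' @param n_trials number of paired trials.
#' @param seed base seed; trial t uses stream (seed, t).
#' @return list: `trials` (data.table, one row per trial and route) and
#'   `summary` (mean absolute error per route).
#' @export
compare_downsampling <- function(callset, readset, target_mean,
                                 n_trials = 20L, seed = 1L) {
  .stopifnot_mcs(callset)
  agg <- aggregate_reads(readset)
  same <- isTRUE(all.equal(
    agg$records[, .(chrom, start, n_meth, n_unmeth)],
    callset$records[, .(chrom, start, n_meth, n_unmeth)]))
  .assert(same, "readset does not aggregate to the supplied call set")
  one <- function(cs) {
    cv <- coverage_of(cs); b <- beta_of(cs)
    list(mean_cov = mean(cv), n_sites = length(cv),
         mean_beta = mean(b), frac_beta01 = mean(b == 0 | b == 1))
  }
  rows <- vector("list", 2L * n_trials)
  for (t in seq_len(n_trials)) {
    cs_c <- thin_counts(callset, target_mean, seed = .substream(seed, "cmp", t, "c"))
    cs_r <- thin_reads(readset, target_mean, seed = .substream(seed, "cmp", t, "r"))
    rows[[2 * t - 1]] <- c(list(trial = t, route = "counts"), one(cs_c))
    rows[[2 * t]] <- c(list(trial = t, route = "reads"), one(cs_r))
  }
  trials <- rbindlist(rows)
  trials[, abs_err := abs(mean_cov - target_mean)]
  summary <- trials[, .(mean_abs_err = mean(abs_err),
                        sd_mean_cov = sd(mean_cov),
                        mean_sites = mean(n_sites)), by = route]
  list(trials = trials[], summary = summary[])
}
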