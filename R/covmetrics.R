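# Coverage, efficiency, conversion and annotation-profile metrics.

#' Coverage summary against a reference CpG set
#'
#' Mean coverage is computed over covered sites only (bedGraph files carry no
#' zero rows), while the cumulative distribution and the >= k-fold fractions
#' are taken over the full reference set, counting uncovered reference CpGs
#' as 0x.  Capture fraction is the proportion of reference CpGs covered at or
#' above `capture_min` (default 1x).
#'
#' @param callset MethylCallSet.
#' @param reference_cpg data.frame/data.table with `chrom`, `start` of every
#'   reference CpG (e.g. a truth table or FASTA scan).
#' @param k_list coverage thresholds for the >= k-fold fractions.
#' @param capture_min coverage threshold defining "captured".
#' @return list of class `CoverageSummary`: `mean_coverage`, `ecdf`
#'   (data.table coverage/cum_fraction over the reference), `frac_ge_k`
#'   (named numeric), `capture_fraction`, `n_reference`, `n_covered`.
#' @export
coverage_summary <- function(callset, reference_cpg,
                             k_list = c(1, 5, 10, 20), capture_min = 1L) {
  .stopifnot_mcs(callset)
  ref <- as.data.table(reference_cpg)[, .(chrom, start)]
  .assert(nrow(ref) > 0L, "reference CpG set is empty")
  r <- callset$records[, .(chrom, start, cov = n_meth + n_unmeth)]
  ref_cov <- r[ref, on = c("chrom", "start")]$cov
  ref_cov[is.na(ref_cov)] <- 0L
  cov_sorted <- sort(ref_cov)
  ecdf_dt <- data.table(coverage = unique(cov_sorted))
  ecdf_dt[, cum_fraction := findInterval(coverage, cov_sorted) / length(cov_sorted)]
  frac_ge_k <- vapply(k_list, function(k) mean(ref_cov >= k), 0)
  names(frac_ge_k) <- paste0("ge", k_list)
  structure(list(
    mean_coverage = if (nrow(r)) mean(r$cov) else NA_real_,
    ecdf = ecdf_dt,
    frac_ge_k = frac_ge_k,
    capture_fraction = mean(ref_cov >= capture_min),
    n_reference = nrow(ref), n_covered = sum(ref_cov > 0L)),
    class = "CoverageSummary")
}

#' Read pairs needed to reach a target mean CpG coverage
#'
#' Linear extrapolation from an observed (pairs, mean coverage) point,
#' rounded up to a whole pair count.
#'
#' @param observed_pairs read pairs sequenced.
#' @param observed_mean_cov achieved mean CpG coverage (> 0).
#' @param target_cov desired mean CpG coverage.
#' @return required read-pair count (numeric, integral value).
#' @export
reads_for_target <- function(observed_pairs, observed_mean_cov, target_cov) {
  .assert(observed_pairs > 0 && observed_mean_cov > 0 && target_cov > 0,
          "all inputs must be positive")
  ceiling(observed_pairs * target_cov / observed_mean_cov)
}

#' Usable-bases fraction
#'
#' Fraction of sequenced bases surviving trimming, mapping, deduplication and
#' filtering, i.e. the bases that inform methylation calls.
#'
#' @param bases_in_retained_reads,total_bases_sequenced base counts.
#' @return fraction in \[0,1\].
#' @export
usable_bases <- function(bases_in_retained_reads, total_bases_sequenced) {
  .assert(bases_in_retained_reads >= 0 && total_bases_sequenced > 0,
          "base counts must be non-negative with a positive total")
  .assert(bases_in_retained_reads <= total_bases_sequenced,
          "retained bases exceed total bases")
  bases_in_retained_reads / total_bases_sequenced
}

#' Spike-in and context conversion report
#'
#' Pooled apparent methylation (sum of methylated counts over total counts —
#' the pooled binomial MLE) per spike-in contig and per cytosine context.
#' For an unmethylated control, conversion efficiency is 1 minus apparent
#' methylation.  A configured contig absent from the call set is reported
#' with NA, not an error.
#'
#' @param callset MethylCallSet (may contain CHG/CHH context records).
#' @param spike_contigs character vector of spike-in contig names.
#' @return list: `per_contig` (data.table contig/n_meth/n_total/
#'   apparent_meth/conversion_efficiency), `per_context` (data.table).
#' @export
conversion_report <- function(callset, spike_contigs = c("lambda", "pUC19")) {
  .stopifnot_mcs(callset)
  r <- callset$records
  per_contig <- rbindlist(lapply(spike_contigs, function(ct) {
    sub <- r[chrom == ct]
    nm <- sum(sub$n_meth); nt <- sum(sub$n_meth + sub$n_unmeth)
    data.table(contig = ct, n_meth = nm, n_total = nt,
               apparent_meth = if (nt > 0) nm / nt else NA_real_,
               conversion_efficiency = if (nt > 0) 1 - nm / nt else NA_real_)
  }))
  per_context <- r[, .(n_meth = sum(n_meth),
                       n_total = sum(n_meth + n_unmeth)), by = context]
  per_context[, apparent_meth := n_meth / n_total]
  list(per_contig = per_contig, per_context = per_context[])
}

#' Mono- and di-nucleotide enrichment of covered bases
#'
#' log2 of nucleotide frequency within the covered intervals over the
#' genome-wide frequency, for A/C/G/T and all 16 dinucleotides (overlapping
#' windows, + strand only).  Zero frequencies are floored at
#' `pseudofrequency` before the ratio.
#'
#' @param covered_intervals data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).  Intervals beyond a contig end are clipped with a
#'   warning.
#' @param fasta path to the reference FASTA.
#' @param pseudofrequency floor applied to both frequencies.
#' @return data.table: `kmer`, `width`, `freq_covered`, `freq_genome`,
#'   `log2_enrichment`.
#' @export
nucleotide_enrichment <- function(covered_intervals, fasta,
                                  pseudofrequency = 1e-6) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  iv <- as.data.table(covered_intervals)[, .(chrom, start, end)]
  .assert(all(iv$chrom %in% names(genome)), "interval on unknown contig")
  lens <- Biostrings::width(genome)[match(iv$chrom, names(genome))]
  if (any(iv$end > lens | iv$start < 0L)) {
    warning("interval(s) extend beyond contig bounds; clipped")
    iv[, start := pmax(start, 0L)]
    iv[, end := pmin(end, lens)]
    iv <- iv[end > start]
  }
  cov_seq <- Biostrings::DNAStringSet(genome[iv$chrom],
                                      start = iv$start + 1L, end = iv$end)
  count_freq <- function(seqs, width) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width))
    counts / max(sum(counts), 1)
  }
  out <- rbindlist(lapply(1:2, function(w) {
    fc <- count_freq(cov_seq, w)
    fg <- count_freq(genome, w)
    data.table(kmer = names(fc), width = w,
               freq_covered = as.numeric(fc), freq_genome = as.numeric(fg))
  }))
  out[, log2_enrichment := log2(pmax(freq_covered, pseudofrequency) /
                                  pmax(freq_genome, pseudofrequency))]
  out[]
}

# single-label assignment by precedence for gene features
.gene_precedence <- c("promoter", "utr5", "exon", "intron", "utr3", "up5kb")

#' Assign annotation labels to call-set sites
#'
#' Each site receives one gene-context label by precedence
#' (promoter > 5'UTR > exon > intron > 3'UTR > up5kb > intergenic) and,
#' independently, one island-context label
#' (island > shore > shelf > open_sea).
#'
#' @param callset MethylCallSet.
#' @param annot AnnotationSet from [generate_annotations()] (or any list with
#'   `features`, `islands`, `shores`, `shelves` data.tables).
#' @return data.table: chrom, start, `feature`, `island_context`.
#' @export
annotation_assign <- function(callset, annot) {
  .stopifnot_mcs(callset)
  sites <- callset$records[, .(chrom, start)]
  sites[, `:=`(qstart = start, qend = start)]  # point query
  label_of <- function(feat_dt, labels_ordered, default) {
    out <- rep(default, nrow(sites))
    if (nrow(feat_dt)) {
      # half-open [start, end) -> closed [start, end - 1] for foverlaps
      f <- copy(as.data.table(feat_dt))[, end := end - 1L][end >= start]
      setkey(f, chrom, start, end)
      ov <- foverlaps(sites, f, by.x = c("chrom", "qstart", "qend"),
                      type = "any", which = TRUE, nomatch = NULL)
      if (nrow(ov)) {
        ov[, rank := match(f$label[yid], labels_ordered)]
        best <- ov[, .(rank = min(rank)), by = xid]
        out[best$xid] <- labels_ordered[best$rank]
      }
    }
    out
  }
  feature <- label_of(annot$features, .gene_precedence, "intergenic")
  isl <- rbind(
    if (nrow(annot$islands)) copy(annot$islands)[, label := "island"],
    if (nrow(annot$shores)) copy(annot$shores)[, label := "shore"],
    if (nrow(annot$shelves)) copy(annot$shelves)[, label := "shelf"],
    fill = TRUE)
  island_context <- label_of(
    if (is.null(isl)) data.table() else isl,
    c("island", "shore", "shelf"), "open_sea")
  data.table(chrom = sites$chrom, start = sites$start,
             feature = feature, island_context = island_context)
}

#' Mean coverage or methylation profile around anchor points
#'
#' Aggregates a per-site value over all (anchor, site) pairs within a
#' symmetric window, in fixed-width bins of the site's offset from the
#' anchor.  Minus-strand anchors are flipped so that positive offsets always
#' point downstream (TSS-oriented curves).
#'
#' @param callset MethylCallSet.
#' @param anchors data.frame with `chrom`, `pos` (0-based) and `strand`.
#' @param window half-width in bp.
#' @param value `"coverage"` or `"beta"`.
#' @param bin_width bin width in bp.
#' @return data.table: `bin_start` (offset of the bin's left edge), `mean`,
#'   `n` (site-anchor pairs in the bin).  Empty (with a warning) if no site
#'   falls in any window.
#' @export
region_profile <- function(callset, anchors, window = 5000L,
                           value = c("coverage", "beta"), bin_width = 100L) {
  .stopifnot_mcs(callset)
  value <- match.arg(value)
  anc <- as.data.table(anchors)[, .(chrom, pos, strand)]
  r <- callset$records[, .(chrom, start,
                           val = if (value == "coverage") n_meth + n_unmeth
                                 else n_meth / (n_meth + n_unmeth))]
  r[, `:=`(qstart = start, qend = start)]  # point query
  win <- anc[, .(chrom, wstart = pos - window, wend = pos + window,
                 pos, strand)]
  setkey(win, chrom, wstart, wend)
  ov <- foverlaps(r, win, by.x = c("chrom", "qstart", "qend"), nomatch = NULL)
  if (!nrow(ov)) {
    warning("no sites fall inside any anchor window")
    return(data.table(bin_start = integer(), mean = numeric(), n = integer()))
  }
  ov[, offset := fifelse(strand == "-", pos - start, start - pos)]
  ov[, bin_start := bin_width * floor(offset / bin_width)]
  out <- ov[, .(mean = mean(val), n = .N), by = bin_start]
  setorder(out, bin_start)
  out[]
}

#' Mean methylation per genomic feature class
#'
#' Unweighted mean of per-site beta values within each gene-context label
#' (the metagene summary).  Labels absent from the call set are reported
#' with NA.
#'
#' @param callset MethylCallSet.
#' @param annot AnnotationSet.
#' @return data.table: `feature`, `mean_beta`, `n_sites`.
#' @export
metagene_summary <- function(callset, annot) {
  lab <- annotation_assign(callset, annot)
  dt <- data.table(feature = lab$feature, beta = beta_of(callset))
  all_labels <- c(.gene_precedence, "intergenic")
  out <- dt[, .(mean_beta = mean(beta), n_sites = .N), by = feature]
  missing <- setdiff(all_labels, out$feature)
  if (length(missing))
    out <- rbind(out, data.table(feature = missing, mean_beta = NA_real_,
                                 n_sites = 0L))
  out[order(match(feature, all_labels))]
}
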