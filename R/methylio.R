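# bedGraph I/O and call-set algebra.
#
# Dialect: the six-column MethylDackel layout
#   chrom  start  end  meth%  n_meth  n_unmeth
# Column 4 is presentation only (beta * 100, rounded); counts in columns 5-6
# are the source of truth and are round-tripped exactly.

#' Read a methylation bedGraph
#'
#' Parses a six-column MethylDackel-dialect bedGraph into a
#' [methyl_callset()].  The percent column is ignored (it is derived from the
#' counts); an optional leading `track` header line is tolerated.  Files
#' ending in `.gz` are read transparently.
#'
#' @param path file path.
#' @param strand strand to assign to every record: MethylDackel bedGraphs do
#'   not carry strand, so single-cytosine files (end = start + 1) default to
#'   `"+"` and merged files (end = start + 2) to `"*"`.  Pass explicitly to
#'   override.  A per-record strand can instead be supplied as an optional
#'   7th column.
#' @param context cytosine context label for the records (default `"CpG"`).
#' @param ... metadata fields forwarded to [methyl_callset()].
#' @return MethylCallSet, sorted by (chrom, start).
#' @export
read_bedgraph <- function(path, strand = NULL, context = "CpG", ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) && grepl("^track", lines[1])) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(methyl_callset(data.table(), context_filter = context, ...))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(bad <- nf < 6L))
    stop("malformed bedGraph line ", which(bad)[1], ": expected >= 6 columns")
  mat <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  n_meth <- suppressWarnings(as.integer(mat[, 5]))
  n_unmeth <- suppressWarnings(as.integer(mat[, 6]))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  bad <- which(is.na(n_meth) | is.na(n_unmeth) | is.na(start) | is.na(end))
  if (length(bad)) stop("malformed bedGraph line ", bad[1], ": non-integer field")
  if (any(n_meth < 0L | n_unmeth < 0L)) {
    stop("negative count on line ", which(n_meth < 0L | n_unmeth < 0L)[1])
  }
  str_col <- if (all(nf >= 7L)) vapply(fields, `[`, "", 7L) else NULL
  rec <- data.table(
    chrom = mat[, 1], start = start, end = end,
    strand = if (!is.null(str_col)) str_col
             else if (!is.null(strand)) strand
             else ifelse(end - start >= 2L, "*", "+"),
    context = context, n_meth = n_meth, n_unmeth = n_unmeth)
  methyl_callset(rec, context_filter = context, ...)
}

#' Write a methylation bedGraph
#'
#' Emits the six-column dialect; column 4 is `round(beta * 100)` so the file
#' is readable by array/sequencing browsers, but counts are what round-trips.
#'
#' @param callset MethylCallSet.
#' @param path output path (`.gz` writes gzip).
#' @param strand_col also write the strand as a 7th column (default FALSE,
#'   matching MethylDackel output).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(callset, path, strand_col = FALSE) {
  .stopifnot_mcs(callset)
  r <- callset$records
  pct <- if (nrow(r)) as.integer(round(100 * r$n_meth / (r$n_meth + r$n_unmeth)))
         else integer()
  cols <- list(r$chrom, r$start, r$end, pct, r$n_meth, r$n_unmeth)
  if (strand_col) cols <- c(cols, list(r$strand))
  out <- do.call(paste, c(cols, sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Merge strand-symmetric CpG records into dinucleotide records
#'
#' A CpG's two cytosines sit at positions `s` (+ strand) and `s + 1`
#' (- strand).  Their counts are summed into one record spanning
#' `[s, s + 2)` with strand `"*"`.  Cytosines observed on one strand only
#' pass through, re-anchored to the + strand C position (a - strand record at
#' `s + 1` becomes `[s, s + 2)`).  Already-merged records are returned
#' unchanged, so the operation is idempotent.
#'
#' @param callset MethylCallSet with CpG-context records.
#' @return MethylCallSet of merged dinucleotide records.
#' @export
merge_context <- function(callset) {
  .stopifnot_mcs(callset)
  r <- copy(callset$records)
  if (!nrow(r)) return(callset)
  # anchor: + strand C position of the dinucleotide each record belongs to
  r[, anchor := fifelse(strand == "-", start - 1L, start)]
  merged <- r[, .(start = anchor[1], end = anchor[1] + 2L, strand = "*",
                  context = context[1],
                  n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
              by = .(chrom, anchor)][, anchor := NULL]
  setcolorder(merged, .mcs_cols)
  out <- callset
  out$records <- merged
  setorder(out$records, chrom, start, strand)
  out
}

#' Sum technical replicates into one call set
#'
#' Union of sites with methylated/unmethylated counts summed per site; this
#' is the standard pre-normalization pooling step for low-coverage technical
#' replicates.
#'
#' @param callsets list of MethylCallSet sharing assay and genome (and merge
#'   state); labs may differ when `allow_lab_mix = TRUE`.
#' @param allow_lab_mix permit pooling across labs (default TRUE).
#' @return MethylCallSet whose `replicate` metadata lists the constituents.
#' @export
merge_replicates <- function(callsets, allow_lab_mix = TRUE) {
  stopifnot(is.list(callsets), length(callsets) >= 1L)
  lapply(callsets, .stopifnot_mcs)
  merged_state <- vapply(callsets, function(x)
    if (nrow(x$records)) all(x$records$strand == "*") else NA, logical(1))
  if (length(unique(stats::na.omit(merged_state))) > 1L)
    stop("cannot pool merged and unmerged call sets")
  assays <- unique(vapply(callsets, function(x) x$meta$assay, ""))
  genomes <- unique(vapply(callsets, function(x) x$meta$genome, ""))
  if (length(assays[!is.na(assays)]) > 1L || length(genomes[!is.na(genomes)]) > 1L)
    stop("replicates must share assay and genome")
  labs <- unique(vapply(callsets, function(x) x$meta$lab, ""))
  if (!allow_lab_mix && length(labs[!is.na(labs)]) > 1L)
    stop("replicates span labs; set allow_lab_mix = TRUE to pool anyway")
  all_rec <- rbindlist(lapply(callsets, `[[`, "records"))
  pooled <- all_rec[, .(end = end[1], context = context[1],
                        n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                    by = .(chrom, start, strand)]
  setcolorder(pooled, .mcs_cols)
  reps <- unlist(lapply(callsets, function(x) x$meta$replicate))
  methyl_callset(pooled, assay = assays[1], genome = genomes[1],
                 lab = if (length(labs) == 1L) labs else paste(labs, collapse = "+"),
                 replicate = paste(reps, collapse = "+"),
                 build = callsets[[1]]$meta$build,
                 context_filter = callsets[[1]]$meta$context_filter)
}

#' Restrict a call set to chromosomes or regions
#'
#' Keeps records whose `start` lies inside a half-open region (or on a named
#' chromosome).  Typical use: limiting comparative analyses to one
#' chromosome.
#'
#' @param callset MethylCallSet.
#' @param chrom character vector of chromosome names, or NULL.
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   or NULL.  When both are given, regions win.
#' @return filtered MethylCallSet (empty, with a warning, if no chromosome
#'   matches).
#' @export
restrict <- function(callset, chrom = NULL, regions = NULL) {
  .stopifnot_mcs(callset)
  r <- callset$records
  if (!is.null(regions)) {
    reg <- as.data.table(regions)
    if (nrow(reg) && any(reg$end < reg$start)) stop("invalid region intervals")
    keep <- rep(FALSE, nrow(r))
    for (i in seq_len(nrow(reg))) {
      keep <- keep | (r$chrom == reg$chrom[i] &
                        r$start >= reg$start[i] & r$start < reg$end[i])
    }
    r <- r[keep]
  } else if (!is.null(chrom)) {
    sel <- which(r$chrom %in% chrom)  # plain which(): `chrom` is also a column
    if (!length(sel) && nrow(r)) warning("no records on requested chromosome(s)")
    r <- r[sel]
  }
  out <- callset
  out$records <- r
  out
}
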