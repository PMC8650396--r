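#' @import data.table
#' @importFrom stats rbinom rpois rnbinom rbeta rnorm runif quantile var sd
#'   median pchisq p.adjust complete.cases setNames cor plogis
#' @importFrom utils head tail
NULL

# Canonical record columns for a per-CpG call set.  Counts are the source of
# truth; beta is always derived, never stored.
.mcs_cols <- c("chrom", "start", "end", "strand", "context", "n_meth", "n_unmeth")

#' Construct a MethylCallSet
#'
#' A `MethylCallSet` holds sorted per-cytosine (or per-CpG-dinucleotide)
#' methylation counts together with the sample metadata needed to track an
#' assay/lab/genome/replicate through a benchmarking pipeline.  Coordinates
#' are 0-based half-open throughout; a merged dinucleotide record spans
#' `[start, start + 2)` and carries strand `"*"`.
#'
#' @param records data.frame/data.table with columns `chrom`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"*"` for merged), `context` (`"CpG"`, `"CHG"`,
#'   `"CHH"`), `n_meth`, `n_unmeth`.  Rows are sorted by (chrom, start) on
#'   construction.
#' @param assay,lab,genome,replicate,build sample metadata strings.
#' @param context_filter which cytosine context the set is restricted to;
#'   `"CpG"` for all primary analyses.
#' @return An object of class `MethylCallSet`.
#' @export
methyl_callset <- function(records,
                           assay = NA_character_, lab = NA_character_,
                           genome = NA_character_, replicate = NA_character_,
                           build = NA_character_, context_filter = "CpG") {
  rec <- as.data.table(records)
  if (nrow(rec) == 0L) {
    rec <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_unmeth = integer())
  }
  missing_cols <- setdiff(.mcs_cols, names(rec))
  if (length(missing_cols))
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  rec <- rec[, .mcs_cols, with = FALSE]
  rec[, `:=`(start = as.integer(start), end = as.integer(end),
             n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  if (nrow(rec)) {
    if (anyNA(rec$n_meth) || anyNA(rec$n_unmeth) ||
        any(rec$n_meth < 0L) || any(rec$n_unmeth < 0L))
      stop("counts must be non-negative integers")
    if (any(rec$n_meth + rec$n_unmeth < 1L))
      stop("emitted records require n_meth + n_unmeth >= 1")
    if (!all(rec$strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
  }
  setorder(rec, chrom, start, strand)
  if (anyDuplicated(rec, by = c("chrom", "start", "strand")))
    stop("duplicate (chrom, start, strand) keys")
  structure(list(
    records = rec,
    meta = list(assay = assay, lab = lab, genome = genome,
                replicate = replicate, build = build,
                context_filter = context_filter)
  ), class = "MethylCallSet")
}

#' @export
print.MethylCallSet <- function(x, ...) {
  m <- x$meta
  cat(sprintf("MethylCallSet: %d records | assay=%s genome=%s lab=%s rep=%s\n",
              nrow(x$records), m$assay, m$genome, m$lab,
              paste(m$replicate, collapse = "+")))
  if (nrow(x$records)) {
    cv <- coverage_of(x)
    cat(sprintf("  mean coverage %.2f | mean beta %.3f | chroms: %s\n",
                mean(cv), mean(beta_of(x)),
                paste(unique(x$records$chrom), collapse = ",")))
  }
  invisible(x)
}

#' Per-site coverage (total observation count)
#' @param x MethylCallSet
#' @return integer vector aligned with `x$records`
#' @export
coverage_of <- function(x) x$records$n_meth + x$records$n_unmeth

#' Per-site methylation proportion (beta value)
#' @param x MethylCallSet
#' @return numeric vector in \[0,1\] aligned with `x$records`
#' @export
beta_of <- function(x) {
  with(x$records, n_meth / (n_meth + n_unmeth))
}

#' Number of sites in a call set
#' @param x MethylCallSet
#' @export
n_sites <- function(x) nrow(x$records)

.is_mcs <- function(x) inherits(x, "MethylCallSet")

.stopifnot_mcs <- function(x) {
  if (!.is_mcs(x)) stop("expected a MethylCallSet")
  invisible(x)
}
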