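# Internal helpers shared across modules.

# Deterministic sub-seed derivation: mixes a base seed with string labels so
# that each (assay, genome, replicate, ...) combination gets its own
# reproducible RNG stream, independent of generation order.  Plain 32-bit
# polynomial string hash; result is a valid set.seed() value.
.substream <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(labels)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# quantile with the package-wide convention: linear interpolation between
# order statistics, inclusive (R type 7).  Centralised so every percentile in
# the package (coverage bins, SNP-probe threshold) uses one rule.
.pctl <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
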