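---
title: "methylbench: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylbench: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylbench)
library(data.table)
```

# Scope

`methylbench` re-implements, as a reusable and tested toolkit, the core
statistical machinery of comparative methylome benchmarking: normalizing
multi-assay per-CpG call sets to a common mean coverage, scoring coverage /
efficiency / concordance, calling per-site differential methylation between
two groups of genomes with cross-assay agreement metrics, and evaluating
methylation microarray matrices with a per-site variance partition plus a
SNP-probe-derived low-variance filter.  Everything upstream of per-CpG
counts (trimming, alignment, deduplication, methylation calling,
basecalling) is out of scope, as are array normalization algorithms
themselves: the array harness evaluates matrices normalized elsewhere.

A synthetic-data module generates seeded inputs with the statistical
structure these analyses assume, so every stage is testable without
external downloads.

# Data model

The unit record is a per-CpG count pair $(n_\mathrm{meth}, n_\mathrm{unmeth})$;
the methylation estimate is the beta value
$\beta = n_\mathrm{meth} / (n_\mathrm{meth} + n_\mathrm{unmeth})$.
Counts are the source of truth throughout: the percent column of the
six-column bedGraph dialect is regenerated on write
(`round(100 * beta)`) and ignored on read, which avoids double-rounding
drift and makes read/write an exact round trip on counts.

Coordinates are 0-based half-open.  Merging strand-symmetric cytosines
(`merge_context()`) sums the + strand C at position $s$ with the − strand C
at $s+1$ into one record $[s, s+2)$; cytosines observed on one strand only
pass through, re-anchored at the + strand position.  The pass-through rule
is a package decision — upstream tooling does not document its behaviour for
lone-strand CpGs — and makes the operation idempotent.

# Coverage normalization by count thinning

`thin_counts()` normalizes a call set to a target mean coverage by
independent binomial thinning: with
$f = \text{target} / \text{current mean}$, retained counts are
$\mathrm{Bin}(n_\mathrm{meth}, f)$ and $\mathrm{Bin}(n_\mathrm{unmeth}, f)$
per site.  The current mean is taken over covered sites (bedGraph files have
no zero rows).  Thinning is unbiased for $\beta$ per site, up to the
zero-truncation effect when a site loses all observations (such sites are
dropped, not back-filled).  Thinning to very low coverage sharpens the
apparent bimodality of the beta distribution — with 5 observations many
sites land exactly on 0 or 1 — which the test suite asserts as a property.

`thin_reads()` is the alignment-level control: whole reads are kept with
probability $f$.  Because one read contributes to every CpG it spans,
retained coverage is correlated along the genome and the achieved mean
coverage is noisier.  For reads averaging $L$ sites with second moment
$E[L^2]$, the error-variance ratio of the two routes is $E[L^2]/E[L]$
(about 12 for the default geometric reads with mean 5), which is why
count-level thinning tracks the target more accurately — the package
reproduces this contrast in `compare_downsampling()`.

# Replicate noise and the expected SD curve

If replicate betas at a site are iid estimates of a common proportion $p$
from $c$ observations each, their variance is $p(1-p)/c$.
`expected_sd_curve()` reports
$\sqrt{\overline{\hat p (1 - \hat p)} / c}$ with $\hat p$ pooled across
replicates — the square root of the expected variance, not the expectation
of the SD.  For $K = 2$ replicates $E[\mathrm{SD}]$ is about
$\sqrt{2/\pi} \approx 0.80$ of this curve (Jensen), so binned mean
replicate SDs plot slightly below it; the Monte-Carlo comparison in the
tests therefore uses the root-mean sample variance, for which the sample
estimator is unbiased.  This mirrors how such curves are drawn over
empirical replicate-SD clouds.

# Differential methylation

Per site, the model is a binomial GLM of $(n_\mathrm{meth}, n_\mathrm{unmeth})$
on a two-level group factor, screened by the coverage filter
*at least `min_samples` (2) samples per group at `min_cov` (5) or more*.
With a single binary covariate the MLE is closed-form — the fitted
proportions are the group-pooled proportions — so `fit_site()` computes the
likelihood-ratio deviance directly from pooled counts:

$$
G^2 = 2\sum_{g \in \{1,2\}}
  \left[ m_g \log \hat p_g + u_g \log (1-\hat p_g) \right]
  - 2 \left[ m \log \hat p_0 + u \log (1-\hat p_0) \right],
\qquad p \sim \chi^2_1 .
$$

This is numerically identical to an IRLS fit (verified against `stats::glm`
to below $10^{-9}$ relative in the tests) but vectorises over sites and is
exact under separation: with $\hat p_g \in \{0, 1\}$ the convention
$0 \log 0 = 0$ gives the finite saturated deviance directly, so no
coefficient capping is needed.  A likelihood-ratio test was preferred over
Wald precisely because Wald degenerates under separation.  P-values are
adjusted by Benjamini–Hochberg step-up (own implementation, cross-checked
exactly against `p.adjust`), significance at $q < 0.05$ by default.  The
effect size is the percent methylation difference (PMD): the difference of
group-pooled proportions.

Cross-assay agreement (`concordance()`) reports, per assay: the DMA size,
the fraction of DMA sites no other assay calls (a pseudo false-positive
rate), the fraction also in DM$k$+ (sites called by $\ge k$ assays; a
specificity), and the fraction of DM$k$+ recovered (a sensitivity).
Because published summaries alternate between "$\ge k$ assays in total" and
"$\ge k-1$ *other* assays", both parameterizations are emitted
(`specificity` / `specificity_other`, etc.) rather than guessing which one
a given printed number used.  `agreement_by_coverage()` cross-tabulates
each assay's DMA sites by (number of assays agreeing) × (median-coverage
bin), restricted to the 5th–95th coverage percentiles.

For arrays, the per-site PMD (`array_pmd()`) is the two-stage estimate:
replicate means per genome, then the difference of group means of genome
means.  On balanced designs this equals the group-effect estimate of a
mixed model with a random intercept per genome (asserted against `lme4` in
the tests); unlike a plain sample-mean difference it weights genomes
equally under unequal replication.

# Array variance partition

For each site, beta-value variance is decomposed under the crossed
random-effects model $y = \mu + a_\text{cell line} + b_\text{lab} + e$
(or $b_\text{assay}$ in the merged sequencing/array mode).  Components are
estimated by method-of-moments (Henderson III): the reductions in sums of
squares $R(a \mid \mu, b)$ and $R(b \mid \mu, a)$ have expectations linear
in the variance components with design-only coefficients, so one set of
projection matrices evaluates the whole sites × samples matrix with three
quadratic forms.  The estimator is deterministic and closed-form — chosen
over REML deliberately, since determinism makes parameter-recovery tests
exact to tolerance — with negative estimates clamped at zero and fractions
renormalized to sum to one.  Missing entries are handled per missingness
pattern (complete cases), and confounded factors (identical groupings) are
rejected.  Recovery of planted components is within ±5 percentage points in
the per-component mean over a few hundred sites; the residual small bias
comes from the ratio nonlinearity and the zero-clamping, both acknowledged.

`pipeline_rank()` ranks externally normalized matrices by the median
per-site variance explained by cell line — the harness reproduces the
comparison procedure, not any particular published ranking.

# SNP-probe low-variance filter

Genotype-reporting SNP probes should read identically for samples of the
same genotype, so within-cluster variance measures pure technical noise.
Clusters are called by naive thresholds per lab.  The printed rule
(< 25% → cluster 1, 25–50% → cluster 2, > 75% → cluster 3) leaves
(50%, 75%] unassigned; the default treats cluster 2 as spanning
[25%, 75%] (presumed typo in the source rule), with the literal rule
available via `rule = "literal"`.  Within each lab, the beta variance of
every (probe, cluster) group with ≥ 2 samples is computed; the threshold is
the 95th percentile of the variances pooled across labs/probes/clusters
(per-lab thresholds behind `per_lab = TRUE`).  Percentiles use linear
interpolation between order statistics (R type 7) — stated explicitly
because percentile conventions differ.  A site is *low-varying* iff its
across-sample variance is strictly below the threshold (a variance exactly
at the threshold is high-varying).

# The synthetic world

`sim_config()` fixes the stated world; its defaults were chosen once:

* **Methylation mixture** — weights (0.35, 0.10, 0.55) over
  Beta(1, 25), Beta(2, 2), Beta(25, 1): bimodal with peaks near 0 and 1, a
  10% intermediate component sustaining a non-empty 20–80% stratum, and a
  global CpG methylation level near 0.59, inside the 45–65% band typical of
  human whole methylomes.
* **Islands** — a deterministic layout (1 kb islands straddling each TSS
  plus intergenic islands; genes every 100 kb, alternating strands) shared
  by the truth table and `generate_annotations()`, with ~30% of sites placed
  inside islands and island sites drawn from an unmethylation-enriched
  mixture (85% unmethylated weight), reproducing promoter hypomethylation.
* **Coverage** — Poisson for even assays; negative binomial with a
  configurable size for heavy-tailed (TruSeq-like) assays; island coverage
  scaled by a per-assay multiplier with the remaining sites rescaled so the
  overall mean stays at the profile's `mean_cov`.  Default mean 30×.  The
  profiles are qualitative emulations: the source material does not state
  per-assay coverage laws, so no claim of calibration is made.
* **Conversion error** — 0.005 (0.5%): a truly unmethylated cytosine reads
  methylated with this probability, applied as
  $p' = p + (1-p)\,\varepsilon$.  Spike-ins: a fully unmethylated
  lambda-like contig (48,502 bp) and a fully methylated pUC19-like contig
  (2,686 bp).
* **Differential sites** — a fraction of sites (default 1%) gets a group-B
  proportion shifted by exactly `dm_pmd` (default 0.3) in a feasible
  direction; all genomes within a group share the site's true proportion.
* **Arrays** — beta = clip$(\mu + b_\text{cell line} + b_\text{lab} + e,
  0, 1)$ with components (0.09, 0.005, 0.01); 7 cell lines (two trios plus
  one unrelated) × 3 labs with (2, 1, 1) replicates = 28 samples, matching
  the 3–6-replicates-per-line scale of a multi-lab array study; 59 SNP
  probes whose founder genotypes are Bernoulli(½) alleles and whose
  children inherit one allele per parent, mapped to cluster centers
  (0.05, 0.5, 0.95) plus technical noise (SD 0.015).

**Reads.**  `generate_reads()` expands a call set into reads covering
contiguous *runs of CpG sites*, such that site-wise aggregation reproduces
the counts exactly (a constructive invariant, asserted everywhere).  The
call set is peeled into coverage layers; runs are cut at a geometric rate,
corrected per layer — sparse layers are run-bound, and the deficit is
redistributed over dense layers through one shared reduced rate — so the
realized mean sites/read tracks the parameter.  Genomic bp span is *not*
modeled (a "read" is a site run, not a 150 bp window), and requested means
far above the feasibility bound set by the layer structure (~8 at 30×
coverage) realize below the request; the default of 5 sites/read sits well
inside the feasible region.

**What a green test does not establish.**  The generator emulates
distributional shape, not any real genome: no sequence-context biases
beyond the island multiplier, no mapping artifacts, no batch structure
beyond the lab component, no hemimethylation, no per-read error model
beyond the scalar conversion error.  Tests against this world validate the
*estimators and bookkeeping*, not assay-specific empirical claims.

# Numerical conventions

* All randomness flows from one integer seed; per-object streams are
  derived by hashing (seed, stage, assay, genome, replicate), so outputs
  are order-independent and byte-identical for a fixed configuration.
* Percentiles: R type 7 everywhere (`.pctl()` internally).
* Sample variance: unbiased, $n-1$ denominator, throughout.
* The 20–80% correlation stratum is judged on the mean of the two assays'
  betas by default (symmetric in the pair); judging on one designated
  reference assay is available via `stratum_on = "reference"` — both
  conventions exist because published figures rarely state which was used.
* Ties/boundaries: stratum bounds inclusive; low-varying uses strict `<`;
  capture threshold defaults to ≥ 1× with `k` configurable (a "min 5×"
  convention also appears in the field, hence the flag).

# Known limitations

* No region-level DMR calling, smoothing, covariate adjustment, or
  overdispersion (beta-binomial) modeling — the per-site model is plain
  binomial by design.
* `thin_reads()` stands in for BAM subsampling; no real BAM/CRAM parsing.
* The variance partition assumes crossed factors without interaction.
* Array normalization pipelines themselves are out of scope.

# A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_sites = 5000)
tr  <- generate_truth(cfg)
g1  <- lapply(paste0("A", 1:3), function(g)
  thin_counts(generate_callset(tr, "EMSeq", g), 20, seed = 1))
g2  <- lapply(paste0("B", 1:3), function(g)
  thin_counts(generate_callset(tr, "EMSeq", g), 20, seed = 2))
res <- dm_test(g1, g2)
res[significant == TRUE][1:3]

bm  <- generate_array(cfg)
thr <- technical_variance_threshold(bm)
table(classify_low_varying(bm, thr$threshold)$label)
```
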