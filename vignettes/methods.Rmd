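---
title: "Models and methods behind poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

# The selection model

A pooled screen is a directed acyclic graph of treatment steps applied to
a mixed population of barcoded deletion strains. `poolscreen` propagates
*relative frequencies* through this graph:

* **Stress edge.** Each strain's frequency is multiplied by its surviving
  fraction for that stress label and the pool is renormalised. Dead cells
  are removed at the stress step itself rather than carried along and
  diluted during outgrowth; at the frequency level the two formulations
  are identical (the fixed 10-generation outgrowth multiplies *every*
  surviving lineage by the same factor), and the removal form is exactly
  computable.
* **Outgrowth edge.** A strain with relative growth rate $r$ (doublings
  per generation relative to wild type) changes by $2^{g(r-1)}$ over $g$
  generations, then the pool is renormalised. The canonical design fixes
  $g = 10$ for every outgrowth step, matching the experimental protocol.

The canonical per-pretreatment design has samples S0 (log-phase pool), S1
(outgrowth control), S2 (low 0.4 mM H2O2 dose alone), S3 (mild
pretreatment alone), and S4/S4A (pretreatment followed by severe 1.0 mM /
1.2 mM H2O2). Severe-dose stress labels are pretreatment-qualified
(`H2O2_1.0mM.NaCl` etc.) so a catalog can encode defects in acquired
resistance that depend on the prior mild stress — the phenomenon the
screen is designed to detect.

On this model the severe-dose fitness score has a closed form: for strain
$i$ with surviving fraction $s_i$,
$f_i(\mathrm{S4vS3}) = \log_2(s_i/\bar s)$ with
$\bar s = \sum_j p_j s_j$ the abundance-weighted mean survival. The test
suite uses this as the oracle for the noiseless round trip through read
counting and through the array path (recovered to $<10^{-9}$).

# Measurement models

**Sequencing.** Reads are `index (6 bp) + common flank + tag (20 bp)`,
drawn multinomially from the pool at a configurable depth, with i.i.d.
base substitutions. Indels and PCR bias are deliberately out of scope:
tags are fixed-length, so mapping is positional. Tag catalogs are
generated at pairwise Hamming distance $\ge 5$, which makes the
protocol's $\le 2$-mismatch mapping unambiguous *by construction*; the
mapper still enforces the uniqueness rule, and demultiplexing applies the
same rule at $\le 1$ mismatch for the 6-bp index. Mismatch tolerance is
mirrored from tag mapping to demultiplexing for symmetry even though the
protocol states the uniqueness condition only for tags.

**Arrays.** Each up and down tag is represented five times. The true
signal $s = \mathrm{scale} \times \mathrm{frequency}$ passes through a
saturating hyperbola $I = I_{max}\, s/(s+K)$; features receive log-normal
noise and, with small probability, are replaced by uniform outliers. The
published protocol applies a saturation "correction factor" without
printing its formula, so simulator and corrector deliberately share one
configurable, invertible response: `desaturate()` computes
$s = K I/(I_{max}-I)$, the exact inverse. Intensities at or above
$I_{max}$ are clipped to a configurable ceiling with a warning.

**Feature summarisation.** "Clear outliers" are made precise as
$|x - \mathrm{median}| > 5\,\mathrm{MAD}$ among a tag's feature
replicates — robust, parameter-light, and directly testable. With MAD
$= 0$ (all replicates identical up to one outlier) only exact-median
values survive, which is the intended behaviour for the 4-good/1-bad
case. Tags with fewer than `min_features` survivors are flagged
low-quality; tags with no usable feature are reported missing, never as
an error.

**Quantile normalisation.** Columns are forced to the common distribution
given by the row-wise mean of per-column sorted values. Ties take the
average rank (the value assigned is the mean of the target values at the
tied positions' bracketing ranks); missing cells are imputed with the
column median for the transformation and restored to missing afterwards.
Both choices are undocumented in the original protocol and are recorded
here as package decisions. Two properties the tests rely on — identical
sorted column vectors and idempotence — hold exactly on tie-free input;
tied values collapse to their average, so these properties hold only up
to tie collapse when ties are present. Up and down tag intensities are
normalised as separate batches, and DAmP arrays should be normalised
separately from the homozygous/heterozygous compilation, mirroring how
the compiled fitness tables were produced.

# Fitness and calling

Fitness is $\log_2((a_N + \epsilon)/(a_D + \epsilon))$ with a
pseudofrequency floor $\epsilon$ (default half a read at the given depth)
keeping dropouts finite. Columns are standardised with the *population*
standard deviation over non-missing strains ("the mean of all strains");
sample sd is available by argument. Where a comparison is measured on
several platforms (Array, sequenced UP and DN tags), the criteria are
applied to the per-replicate platform consensus (their mean) — whether
the original thresholds were applied jointly or per platform is
unstated, so both modes exist and consensus is the default.

The caller follows the published four criteria literally; two details are
package decisions:

* Criterion 3 ("defect at the low dose *less than* at the severe dose")
  is compared on signed consensus fitness with strict inequality, so ties
  break toward exclusion.
* The published lists were "expanded by manually adding strains whose
  fitness phenotypes were highly correlated with identified mutants" —
  irreproducible as literal curation. `expand_by_correlation()` makes it
  an algorithm: uncentered Pearson $r \ge 0.9$ against any called
  strain, guarded by criterion 1 in at least one replicate so expansion
  cannot recruit strains without a severe-dose defect. Expanded calls are
  flagged in the audit; stringent-only mode is the default.

Low-dose sensitivity is a per-strain one-sided one-sample t-test across
the pooled S2vS1 replicate columns with Benjamini–Hochberg correction
(the publication names only "FDR < 0.05"; a signed-rank alternative is
available). Strains whose replicate values are identical are handled by a
degenerate branch (p = 0 if the common value is negative, else 1) rather
than an undefined t statistic.

`apply_exclusions()` then removes from a call set (a) strains with equal
fitness defects at the low and severe doses — implemented as strains in
the low-dose-sensitive set whose severe defect does not exceed their
low-dose defect by at least 2 severe-column standard deviations, plus any
numerically equal pair — and (b) strains sensitive to the mild stress
alone ($z(\mathrm{S3vS1}) \le -1$ in $\ge 2$ replicates). The margin form
is a package decision: it is what separates a genuine acquisition defect
(severe $\gg$ low-dose defect) from general H2O2 sensitivity in the
presence of replicate noise, and the margin of 2 sd keeps planted
uniformly-sensitive strains out of the call sets with high probability
while leaving genuine defects (severe excess $\approx 2.5$ sd by
construction) untouched.

For single-replicate libraries the two routes are both implemented: the
stringent criteria at *both* severe doses (1.0 and 1.2 mM), or mutants of
the same gene passing in $\ge 2$ libraries (e.g. heterozygous and DAmP).
Gene-level reporting prefers homozygous > DAmP > heterozygous evidence.

# The synthetic world

`synth_catalog()` + `simulate_screen()` state one fixed world:

* **Pool composition.** Default test-scale pools of 500 strains (the
  full-scale 4,800/1,300/1,140 homozygous/heterozygous/DAmP composition
  is available via `full_pool_catalog()`); starting frequencies
  log-normal with CV 0.15 ("roughly equally represented").
* **Baseline survivals.** Mild pretreatment 0.95, low 0.4 mM dose 0.9,
  severe 1.0 mM after pretreatment 0.8, 1.2 mM 0.7 — consistent with a
  severe dose that kills most *untreated* cells but leaves pretreated
  wild-type cells >80% viable, and a mild dose that kills few.
* **Noise.** Two log2-normal stress-response factors per strain and
  stress: a persistent one (sd 0.2, drawn once per screen) for the
  biological diversity of deletion-strain stress fitness, and a
  per-experiment one (sd 0.2) for dose/handling variation between
  replicate selections. They model net enrichment through stress plus
  recovery, so the effective multiplier may exceed 1 (faster post-stress
  recovery) even though catalog survivals are proper fractions. The
  persistent factor is applied to the *null background only*: planted
  strains are defined by their planted deficit alone, so recovery is
  measured against an exactly stated truth. Sequencing adds multinomial
  counting noise at the configured depth; neither depth nor array
  background is stated by the original protocol, so both are
  configuration, not claims.
* **Planted effect sizes.** The planted severe-dose deficit is stated in
  column-sd units ($e = 2.5$). Because planting a fraction $\pi$ of
  outliers itself inflates the column sd, the log2 deficit is derived
  analytically rather than tuned:
  $\sigma_{col}^2 = \sigma_0^2 + \pi(1-\pi)\Delta^2$ with
  $\Delta = e\,\sigma_{col}$ gives
  $\Delta = e\,\sigma_0/\sqrt{1 - e^2\pi(1-\pi)}$, where
  $\sigma_0^2 = \sigma_{rep}^2 + \sigma_{strain}^2$ is the base column
  variance. Pretreatment-sensitive confounders receive the analogous
  deficit on the mild-stress label; uniformly-sensitive confounders
  receive the severe-dose deficit at both the low and severe doses.

**What a green recovery test establishes — and what it does not.** The
generator emulates frequency dynamics, replicate/biological noise, and
counting noise. It does not emulate PCR amplification bias, index
hopping, strain cross-contamination, batch structure between arrays, or
biologically correlated phenotypes (planted classes are independent of
the background). Recovery of planted defects (sensitivity $\ge 0.9$ at
screen level, false-call fraction $\le 0.1$, zero confounder calls)
therefore validates the *pipeline logic and thresholds*, not performance
on any real library.

# Set and network statistics

Hypergeometric enrichment uses the upper tail $P(X \ge k)$ with the
universe as an explicit, required input (whether the original analysis
used the whole genome or only assayed strains as its universe is
unstated). The Bonferroni factor is the number of categories in the
collection — all tested, not only those with non-zero overlap —
conservative and reproducible. Clustering uses
$d = 1 - \sum xy/\sqrt{\sum x^2 \sum y^2}$ (uncentered Pearson, the
metric named by the original analysis) with average linkage, the default
of the clustering tool it cites; the linkage is configurable.

The interaction permutation test draws `n_perm` same-size gene sets
uniformly from a sampling frame and counts trials with at least the
observed number of internal edges. The frame defaults to the graph's
nodes plus any supplied assayed genes (so unannotated genes can be
drawn); whether the original sampling frame was the genome or the
interaction-network node set is unstated. The add-one estimator
$(1 + t)/(n_{perm} + 1)$ is the default so $\hat p$ is never zero; the
raw fraction, which the publication reports, is available with
`add_one = FALSE` and is what the exhaustive-enumeration acceptance
check compares against.

# Validation assays

The survival score sums (pretreated − mock) viability over the severe
dose ladder; the dose count is always taken from the input (the source
protocol mentions both 11 and 12 doses), and fractions are the default
unit (percent is the same score times 100). Competition fitness is
defined on the change in log2 odds of the GFP fraction, normalised by
the wild-type control mixture — the original describes this comparison
qualitatively; the odds-ratio form is the package's formalisation and
makes the score invariant to the 1:5 mixing ratio, which the tests check
over a grid of starting fractions.

# Numerical choices and degenerate inputs

* Fitness floor: half a count at the configured depth; configurable.
* `standardize()` errors on zero-sd columns rather than returning NaN.
* Zero column totals in abundance normalisation are errors (an empty
  sample is a configuration problem, not a measurement).
* All-zero profiles are dropped from clustering with a warning
  (undefined uncentered correlation).
* Empty FASTQ input yields all-zero counters; malformed reads are
  counted, never fatal.
* Seeds: every stochastic entry point takes an explicit integer seed;
  `simulate_screen()` derives sub-seeds from one stream so a single seed
  reproduces the entire screen.

# Known limitations

* The correlation-expansion step is a reproducible surrogate for a
  manual curation step; call counts from expanded mode are not expected
  to match any manually curated list exactly.
* The saturation correction is a documented stand-in for an unpublished
  formula; real array data corrected with a different response will not
  round-trip exactly.
* The low-dose FDR statistic is a choice among reasonable tests; only
  the FDR threshold itself is sourced.
* Criteria are applied to platform-consensus fitness by default; the
  original analysis may have accepted strains passing on any single
  platform ("microarray and/or sequencing"), which would call more
  strains.
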