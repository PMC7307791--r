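---
title: "Calling DMRs and classifying their recovery dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling DMRs and classifying their recovery dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrdyn)
```

## The analysis this package implements

Reduced representation bisulfite sequencing (RRBS) yields, per CpG
dinucleotide and biological replicate, a pair of counts: methylated reads
and total reads.  `dmrdyn` implements a threshold-cascade analysis of such
data for exposure studies with recovery timepoints — e.g. sperm collected
right after a smoke-exposure period and again one or more spermatogenic
cycles later — together with the comparison statistics used to relate
methylation effects across tissues, generations and genotypes.

The cascade has four stages, each an explicit, parameterized rule
(`filter_params()`):

1. **Scoreability.** A CpG is scoreable for a group when its read coverage
   is strictly greater than 8 in at least 4 biological replicates.  Both
   numbers are parameters; the defaults implement the strict reading of
   "greater than 8" (so 8 reads fail, 9 pass).  Zero-coverage cells are
   *missing*, not "failing the filter": missingness is a property of the
   data, scoreability a property of the rule.
2. **Per-CpG differential calls.** For sites scoreable in both compared
   groups, the group methylation level is the unweighted mean over passing
   replicates of the per-replicate fraction `meth / total`, and a site is
   differentially methylated when `|delta| > 0.05` (strict), with
   `delta = test - control` as an absolute (percentage-point) difference.
3. **Proximity binning.** Scoreable CpGs are merged greedily along each
   chromosome while consecutive gaps are at most `max_bin_gap` (default
   250 bp).  Only bins with at least 3 CpGs and a span strictly greater
   than 50 bp are analyzed.  The span counts the final CpG dinucleotide
   (`end = last position + 2`), giving the half-open interval an explicit
   right edge; a 3-CpG bin at positions 100/120/148 therefore spans
   exactly 50 bp and is excluded, while 100/120/149 is included.
4. **Regional DMR calls.** A region is a bona fide DMR when at least one
   third of its CpGs are differentially methylated (inclusive, so 1 of 3
   qualifies) *and* the regional `|delta| > 0.05` (strict), where the
   per-sample regional level is the unweighted mean over member CpGs of
   the per-CpG fractions and group levels average those per-sample values.

No significance test takes part in the calling decision.  A two-sided
Welch t-test on the per-sample regional fractions is reported alongside
every region (`aux_p`) because downstream variation profiling refers to
regional significance, but it never gates a call; at the default noise
conditions (30x coverage, beta-binomial rho 0.1, 10 replicates) the
cascade flags roughly 5% of null regions, and the package's calibration
tests pin that rate rather than hide it.

### Recovery dynamics

Given region tables for the exposure timepoint (t0) and a recovery
timepoint, both called against the same control on one shared binning,
`classify_recovery()` assigns each region that is a DMR in at least one
table exactly one status:

* **shared** — DMR at both timepoints;
* **recovered** — DMR at t0 only;
* **new** — DMR at the recovery timepoint only.

Region identity is by exact coordinates from a single binning over CpGs
scoreable in *all* compared groups; comparing region sets across
timepoints is only well-defined on such a common universe, and the
classifier refuses tables whose regions overlap without coinciding.
Status ignores the direction of change (a shared region that flipped sign
is flagged `discordant` rather than reclassified), and the recovered
fraction is reported with t0 DMRs as the denominator —
`recovered / (recovered + shared)` — with `new` regions counted
separately.

Stratification crosses the control-group baseline class (hypo < 25%,
intermediate, hyper > 75% methylation; boundaries assigned inward, so a
mean of exactly 25% is intermediate) with the direction of change, the
same six classes used to ask whether extreme-baseline regions whose
methylation moved toward the middle are the ones that recover.
CpG-density and replicate-variation profiles summarize the labeled
classes and compare them with two-sided Wilcoxon rank-sum tests; the test
choice is a stand-in, since no test is canonical for these contrasts, and
fully tied inputs are reported as degenerate (p = 1) rather than NaN.

### Enrichment and concordance statistics

* `permutation_enrichment()` — the observed statistic counts *distinct*
  DMRs overlapping any TSS window (half-open semantics; abutment is not
  overlap).  The null re-places the window set uniformly at random,
  length-preserving, with chromosomes weighted by their number of
  placeable start positions — the behaviour of the standard genome-wide
  interval shuffle.  The empirical p-value uses the add-one rule
  `p = (1 + #[null >= obs]) / (n_perm + 1)`, so it is never exactly zero.
  The shuffled set is the window set by default (matching a design where
  the TSS windows are the randomized annotation), with an option to
  shuffle the DMRs instead.  All permutations are placed in one
  vectorized draw and counted through a single interval join, which keeps
  thousand-permutation runs in the seconds range.
* `hypergeometric_overlap()` — upper-tail probability of the observed
  overlap between two region or gene sets in a finite universe.  The
  universe is explicit: for DMR sets, regions analyzed in both
  comparisons; for DE sets, genes tested in both.
* `delta_correlation()` — Pearson correlation of per-region methylation
  deltas (or per-gene log2 fold changes) over items present in both
  comparisons, restricted by default to the union of DMRs when DMR flags
  are available, with the unrestricted variant one argument away.

### Expression variation

`normalize_counts()` implements median-of-ratios normalization (the
median taken on the log scale, numerically identical to DESeq2's
`estimateSizeFactorsForMatrix`).  `de_filter()` applies the strict DE
rule `|log2FC| > 1` and unadjusted `p < 0.05`.  `stand_in_de_test()` is
a deliberately plain Welch t-test on `log2(normalized + 1)` provided so
synthetic end-to-end runs need no external DE engine; it is documented as
non-equivalent to a negative-binomial method, and real studies should
supply an externally computed statistics table.
`variation_comparison()` compares per-gene spread (within-group SD of
log-normalized counts by default; CV and MAD switchable) between groups
with a paired Wilcoxon signed-rank test — the "variation" metric behind
statements like "globally elevated expression variation" is not uniquely
defined in the literature, so the choice is explicit and swappable.

## The synthetic methylome generator

Because raw sequencing data cannot ship with a package, every stage is
exercised against a generator whose defaults *are* the emulated study
conditions and whose injected effects are recorded in a ground-truth
ledger:

* **CpG landscape** — superposition of a sparse background Poisson point
  process (mean spacing 400 bp) and island-like clusters (rate 1/5000 bp,
  ~8 CpGs at ~15 bp spacing), giving the density heterogeneity that makes
  proximity binning meaningful.  CpG starts are at least 2 bp apart.
* **Baselines** — drawn from a bimodal mixture (40% hypo at mean 8%, 20%
  intermediate at 50%, 40% hyper at 92%; beta concentration 60), matching
  the bimodal character of mammalian CpG methylation.  Baselines are
  region-coherent within candidate bins so regional analyses see
  realistic spatial correlation.
* **Counts** — total reads per cell are shifted Poisson (mean 30, never
  zero); methylated reads are beta-binomial with between-replicate
  correlation rho = 0.1.  Published analyses of this style report no
  replicate-variance figures, so rho is a calibration choice, stated
  here once: it produces per-replicate fraction SDs of ~0.1–0.18
  at intermediate methylation, enough that the threshold cascade's
  behaviour under noise is visible rather than idealized.
* **Effects** — `injected_dmr_count` candidate bins (default 75) receive
  a methylation delta of magnitude 0.25.  The default direction policy is
  *inward*: hypomethylated regions gain, hypermethylated regions lose,
  intermediate regions get a random sign.  Methylation fractions are
  bounded, so effects at the extremes can only move toward the middle;
  this mirrors the observed predominance of gains at hypo- and losses at
  hyper-methylated regions.  Under the `random` policy, effects pushing
  the fraction outside [0, 1] are clipped and the clipping recorded.
* **Dynamics** — each effect is `persist` (present at every timepoint),
  `decay` (exposure timepoint only) or `emerge` (recovery timepoints
  only), in equal proportions by default.  These map one-to-one onto the
  observed shared / recovered / new classes, which is what makes
  classification accuracy scoreable.  `dynamics_baseline_coupling`
  (default 0.8) assigns decay preferentially to extreme-baseline inward
  effects, encoding the hypothesis that extreme-methylation regions are
  buffered and snap back — this is the mechanism the stratified recovery
  analysis is designed to detect, injected deliberately so the analysis
  can be validated against a known signal.
* **Annotation and expression** — TSS windows are fixed 2 kb promoter
  proxies with a controllable fraction placed over truth regions;
  expression counts are negative-binomial with log-normal means,
  per-gene dispersion around 0.05, injected log2 fold changes, and an
  optional dispersion inflation factor for one group (the generator's
  analogue of globally elevated expression variation).
* **Determinism** — one root seed fans out to named substreams
  (landscape, truth, counts, annotation, expression, shuffle) via
  `substream_seed()`, so identical configurations reproduce
  byte-identical outputs and individual stages can be regenerated
  independently.

What the generator does *not* emulate: read-level artifacts (bisulfite
conversion failure, mapping bias, strand effects), fragment-level
coverage correlation, SNP-overlapping CpGs, and genome-scale annotation
structure.  Passing tests therefore demonstrate that the *rules and
statistics* behave as specified under realistic count noise — not that
any biological conclusion transfers to real data.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere inside the package;
  conversion happens exactly once at file boundaries (Bismark coverage
  files are 1-based, BED is native).  A double-conversion guard is part
  of the I/O tests.
* The binning gap default of 250 bp approximates RRBS fragment
  clustering; no canonical value exists, so it is an exposed parameter
  rather than a constant.
* Scoreability for a two-group comparison requires the coverage rule in
  each group separately (`both_groups`); whether pooling across all
  samples was intended is genuinely ambiguous, so `all_samples` is
  available as a mode.
* Group regional levels average per-replicate fractions rather than
  pooling reads, because replicate-level variation is itself an analysis
  output; pooled counting would erase the quantity being studied.
* The one-third rule is inclusive (1 of 3 qualifies): "one third needed
  to be differentially methylated" reads as a minimum attained at
  equality.
* Ties at the baseline-class boundaries go to intermediate, mirroring
  the strict "< 25%" / "> 75%" definitions of the outer classes.
* Degenerate inputs are handled explicitly: empty coverage files parse
  to empty record sets, all-tied rank tests report p = 1, empty recovery
  classes skip their test with a flag, and zero-variance genes get p = 1
  in the stand-in DE test.

## Problem sizes used by the test suite

The packaged analyses run on simulated chromosomes of a few megabases:
oracle-equivalence checks use 50 random chromosomes of up to 500 CpGs
against an independently coded brute-force caller; dynamics recovery uses
the default design (75 injected regions, 25 per class, 3 Mb of genome,
~12,000 CpGs, 30 samples); the stratified-recovery analysis uses 300
injected regions on 6 Mb to stabilize per-stratum fractions; permutation
calibration uses 200 independent null datasets at 199 permutations each.
These sizes keep the full suite in the minutes range while leaving every
statistical check adequately powered.

## Known limitations

* The cascade inherits the limitations of fixed-threshold calling: no
  error-rate control, sensitivity to coverage and replicate noise (the
  ~5% null region rate above), and no smoothing or shrinkage.  That is
  by design — the package reproduces a specific published rule set — but
  users wanting inferential calls should look to beta-binomial or
  HMM-based DMR callers.
* `stand_in_de_test()` is not a substitute for a proper DE analysis.
* Strand is ignored (CpGs are strand-collapsed sites) and CpH
  methylation is out of scope.
* The shuffle null is unaware of GC content, gaps and annotation
  structure, exactly like the genome-wide shuffle it mirrors.

## A worked example

```{r example, eval = FALSE}
library(dmrdyn)

layout <- genome_layout(c(chr1 = 1.5e6, chr2 = 1.5e6))
config <- sim_config(seed = 1)          # 25 regions per dynamics class
report <- run_recovery_analysis(layout, config)
report
report$strata
report$dynamics_accuracy
```
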