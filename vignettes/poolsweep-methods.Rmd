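---
title: "Methods: pool-seq sweep scans with poolsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq sweep scans with poolsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

## The problem and the model

`poolsweep` contrasts two pools of a species bred for different states of
a trait — group A carries the selected state, group B is the control —
using only per-site allele read counts. Two window statistics are
combined:

**Pooled heterozygosity.** For a window's SNPs, let $a = \sum n_{MAJ}$ and
$b = \sum n_{MIN}$ be the summed major- and minor-allele read counts in
one group. Then

$$H_P = \frac{2ab}{(a+b)^2} \in [0, 0.5],$$

maximal when major and minor reads balance and 0 when the group carries
only major alleles. A sweep in group A drives $H_{P,A}$ down, so we score
$\ln(H_{P,B}/H_{P,A})$: positive values mean diversity loss in the
selected group. The ratio orientation (control over selected) keeps sweep
signals in the upper tail.

**FST.** Per site, with minor-allele read fractions $p_1, p_2$ and
haploid pool sizes $n_1, n_2$, the default Hudson-type estimator is

$$\text{num} = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}, \qquad
\text{den} = p_1(1-p_2) + p_2(1-p_1),$$

aggregated per window as $\sum \text{num} / \sum \text{den}$
(ratio of sums, the recommended aggregation for window scans; per-site
values may be negative). A `wright_mean` variant without the sampling
correction is available. Read fractions stand in for allele frequencies —
the pool-seq approximation — and the haploid sizes default to 800 and 400
chromosomes (40 and 20 pools of 10 diploid animals).

Both statistics are computed in 50-kb windows sliding by 10 kb, windows
with fewer than `min_sites = 10` informative SNPs are discarded, and the
retained vectors are Z-transformed genome-wide with the sample ($n-1$)
standard deviation. Windows with $Z(F_{ST}) > 5$ **and**
$Z(H_P\ \text{ratio}) > 5$ (strict inequalities, intersection of the two
outlier sets) become candidates; overlapping or abutting candidates merge
into regions (`max_gap = 0` by default — at a 10-kb step adjacent signal
windows always overlap), which are annotated with genes overlapping by at
least 1 bp.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_size` / `step` | 50 kb / 10 kb | scan resolution; window edges define reported region bounds |
| `min_sites` | 10 | guards against windows whose statistics rest on a handful of SNPs |
| `z_cutoff` | 5 | outlier threshold on both Z-scores |
| `hp_floor` | 1e-4 | substituted for a zero window HP before the log, so complete sweeps give large finite ratios instead of infinities |
| `haploids_A/B` | 800 / 400 | chromosomes per pool group, used by the FST correction and the simulator |
| QC `max_error_rate` | 0.01 | site quality; Phred < 20 fails |
| QC `min_spacing` | 5 bp | SNP clusters closer than this are removed symmetrically |
| QC depth factors | 1/3 and 2 | per-group depth bounds around the group mean |

Design choices where the conventions are genuinely open:

* *Quality rule.* "Error rate above 1%" is mapped to Phred site quality
  via the standard correspondence $10^{-q/10}$, giving the q ≥ 20 rule;
  the threshold is configurable.
* *Spacing rule.* All members of a < 5 bp cluster are removed, because
  clustered SNP calls usually flag local misalignment and there is no
  principled reason to keep one member; `spacing_mode = "keep_first"`
  implements the alternative.
* *Depth rule.* "Support" is read as total site depth per group, the
  conventional meaning in SAMtools-era filters; the mean is taken over
  the post-spacing site set, per group, with inclusive bounds.
* *QC attribution.* Filters run quality → spacing → depth and a site is
  counted against the first filter it fails, so report counters always
  sum to the input count.
* *FST estimator.* Hudson-type with ratio-of-sums aggregation is the
  default, the standard recommendation for two-population window scans;
  the estimator is pluggable.
* *Region bounds.* Reported as outer bounds of member windows, so region
  edges land on window-grid multiples.
* *Minimum region length.* `filter_regions(min_length = )` defaults to 0;
  long thresholds (e.g. 200 kb) can separate sustained sweeps from short
  drift-fixed segments, but short true regions would be lost, so the
  choice is left to the analyst.
* *ddCt calibrator.* The control-group sample at the earliest fetal stage.
  The reported selected/control ratios are computed directly from dCt
  differences, so the calibrator cancels algebraically and its choice
  only rescales per-sample folds.
* *Group test.* Two-sided Welch t-test on per-sample dCt values, which
  are on an approximately normal scale; the stage association is a
  Spearman correlation of fold against fetal length.

## What the simulator emulates — and what it does not

`simulate_sites()` draws SNP positions as a Poisson process (default
1/500 bp), background frequencies from a symmetric Beta(0.2, 0.2) — the
U-shaped marginal typical of site-frequency spectra — and per-group
frequencies as logit-jittered copies (`drift_sd = 0.2`). Reads are
sampled in two stages: a pool frequency from Binomial(haploids, freq),
then reads from Binomial(Poisson(25) depth, pool frequency). The
two-level draw reproduces the extra count correlation that finite pools
of 10 animals induce in real pool-seq; a direct binomial on the
population frequency would understate it. Site qualities are Normal(60,
15) truncated at zero, so a realistic few percent of sites fail the
quality filter.

Inside a sweep interval the selected-group frequency is moved toward the
nearer boundary by exactly solving $p'(1-p') = r\,p(1-p)$ for the
heterozygosity-retention factor $r$ (`het_reduction`), then displaced a
further `divergence_shift` away from the control frequency, clamped to
[0, 1]. The default study design — one 10-Mb contig, one 300-kb sweep
with $r = 0.1$ and shift 0.3 — gives the analysis scripts and validation
suite a signal comparable to a strong artificial-selection hit, at a
problem size (about 20,000 SNPs, 996 windows) that runs in seconds.

The simulator models marginal allele frequencies and read counts only. It
does **not** model linkage disequilibrium or genealogies (no coalescent),
mapping or base-calling error structure, indels, or reference bias.
Passing the planted-sweep tests therefore shows the scan statistics and
bookkeeping are correct under the model the method itself assumes; it
does not certify behaviour under alignment artefacts or complex
demography, which real data can add.

`simulate_qpcr()` generates one sample per group and stage with
triplicate Ct replicates: a flat reference gene, a target whose Ct rises
with fetal length (expression falling with development) and drops by
`group_effect_dct` in the selected group — so the true log2 fold ratio
equals `group_effect_dct`.

## Numerical choices and degenerate inputs

* Sites with zero reads in either group are dropped before QC: both
  statistics are undefined there.
* Major/minor orientation is fixed once from pooled (A+B) counts, ties
  toward the reference allele, so both groups score the same allele
  partition; swapping group labels then negates every `ln_hp_ratio`
  *exactly* (the ratio is computed as a difference of logs) and leaves
  FST bit-identical (the correction terms are grouped commutatively).
* Window sums are plain slice sums over the sorted site table, so the
  engine is bit-identical to a from-scratch per-window recomputation.
* `z_transform` refuses vectors with fewer than two finite values or zero
  dispersion rather than returning NaN.
* The Z-transformation is genome-wide and includes outlier windows, which
  inflates the standard deviation: once a sweep's windows are a fraction
  $f$ of all retained windows, their Z-scores saturate near
  $\sqrt{(1-f)/f}$ regardless of signal strength. Consequences: (i) Z
  grows with sweep strength only below saturation, and (ii) detection at
  $Z > 5$ needs the swept fraction to stay under roughly 1/26 of the
  genome. This is a property of the published scan design, not of this
  implementation; simulated genomes must be long enough relative to their
  planted sweeps.
* Determinism: one integer seed drives every draw; per-contig substreams
  are derived from it, and identical configuration plus inputs give
  byte-identical output files.

## Known limitations

Haplotype-based statistics (iHS, XP-EHH), permutation significance and LD
are out of scope. The Z > 5 rule is an outlier heuristic, not a
calibrated test; with ~1000 windows the null suite observes zero dual
outliers, but genome-wide error rates on real data depend on
autocorrelation between overlapping windows. Allele frequencies from read
fractions ignore unequal individual contributions within a pool beyond
the two-level binomial. The ddCt module assumes perfect amplification
efficiency (the classical 2-fold-per-cycle model).
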