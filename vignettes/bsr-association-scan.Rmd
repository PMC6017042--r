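---
title: "Methods: the bulked-segregant ED scan and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bulked-segregant ED scan and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrscan)
```

## The design and the statistic

The package analyses a four-pool bulked-segregant RNA-seq design: two
parents (`T01`, `T02`) and two bulks of phenotypically extreme F1
individuals (`T03`, `T04`). In an outcrossing species both parents are
heterozygous at many sites, so the mapping design is a pseudo-testcross:
an informative SNP is heterozygous in one parent and homozygous in the
other, and segregates 1:1 in the F1. At SNPs linked to the selected trait
the two bulks diverge in allele frequency; elsewhere they differ only by
the sampling noise of finite bulks and finite read depth.

At each SNP the scan statistic is the Euclidean distance between the two
bulks' base-frequency vectors over {A, C, G, T}. Frequencies, not absolute
depths, enter the distance so that depth differences between the libraries
cancel. ED lies in $[0, \sqrt 2]$: 0 for identical base compositions,
$\sqrt 2$ for opposite fixed alleles. The monotone transform ED$^k$
(default $k = 5$) is reported alongside; it shrinks the dense background of
small distances relative to true signal but cannot change any ranking.

## Filters

Three filters precede the statistic, in this order:

1. **Read support** (`min_support = 3`): every pool must have at least 3
   reads at the locus. The statistic needs defined frequencies in both
   bulks, and the Mendelian filter needs parental calls, so by default the
   rule applies to all four pools (`support_scope = "all_pools"`); a
   bulks-only variant is available for datasets with thin parents.
2. **Parent-bulk Mendelian consistency**: an allele observed in a bulk
   (frequency at or above the minor-allele floor, default 0.1) must be
   present in the parental allele set. The default pairing,
   `both_parents`, checks each bulk against the union of both parents —
   the weakest assumption that is always valid for an F1, since every F1
   allele comes from one of the two parents. Single-parent pairings
   (`as_printed`, `phenotype_matched`) are provided for users who want a
   stricter, assumption-laden rule, but they over-filter legitimately
   segregating sites whenever the informative parent is on the other side
   of the pairing, which is why they are not the default.
3. **Bulk consistency**: loci at which the bulks have identical observed
   allele sets *and* ED below `consistency_eps` ($10^{-6}$) carry no
   discrepancy and are dropped. The survivors define $M$, the genome-wide
   count of bulk-discrepant SNPs.

The minor-allele floor (0.1) absorbs sequencing error without a base-quality
model: at a typical depth of 50, a 1% uniform miscall rate essentially never
lifts a spurious base to 10% frequency, while genuine segregating alleles in
a 1:1 design sit far above it.

## Thresholding and enrichment

Loci with statistic $\ge$ `threshold` are candidate association loci. The
default compares **raw ED** against 0.74. The threshold could in principle
be applied on the ED$^5$ scale instead (`threshold_on = "ed_powered"`);
we default to the raw scale because 0.74 is a meaningful raw-ED quantile
(0.74 on the ED$^5$ scale would correspond to a raw ED of about 0.94,
practically fixed opposite alleles, and would almost never fire at realistic
depths). The comparison is inclusive (`>=`) so that a locus sitting exactly
at the threshold is not dropped by floating-point rounding.

With $M$ discrepant loci genome-wide of which $K$ are candidates, a unigene
carrying $N$ loci with $Y$ candidates is scored by the upper-tail
hypergeometric probability
$$P \;=\; 1 - \sum_{x=0}^{Y-1} \binom{K}{x}\binom{M-K}{N-x}\Big/\binom{M}{N},$$
the chance of $\ge Y$ candidates among $N$ draws without replacement if
candidates were scattered at random. $P$ is corrected across unigenes by
Benjamini–Hochberg (via `stats::p.adjust`), and unigenes with FDR strictly
below `fdr_cutoff = 0.01` are declared significant.

### Numerical choices

* `hypergeom_tail` sums the upper tail directly in log space
  (`lchoose` + log-sum-exp) rather than computing $1 - \text{lower tail}$,
  which would lose all precision exactly where it matters (small $P$). A
  single code path serves all $M$; it agrees with exhaustive
  binomial-coefficient enumeration to well below $10^{-10}$ for every valid
  configuration with $M \le 30$ (tested), and with `stats::phyper` on larger
  random cases.
* Results are clamped to $[\texttt{.Machine\$double.xmin}, 1]$: a printed
  $P$ of exactly 0 is always a rounding artefact — the finite-population
  probability cannot be exactly zero — so the smallest representable
  positive value is reported instead and itself flags the underflow.
* When $K = 0$ (no candidates anywhere) every $P$ is 1 by construction and
  the scan completes without error; an empty post-filter locus set is an
  explicit error, since the scan has nothing to say.
* Output ordering is canonical (unigene id in C-locale order, then
  position) and numbers are formatted with `%.10g`, so identical input and
  configuration yield byte-identical output files.

## The simulator

`simulate_dataset()` generates the data structure the scan assumes, with
truth labels, so that every stage is testable without any sequencing data:

* Every locus is an informative pseudo-testcross SNP: one parent
  heterozygous ref/alt (chosen at random), the other homozygous reference.
  The Mendelian expectation of the alternate-allele frequency in an
  unselected bulk is therefore 0.25. Doubly heterozygous (intercross) loci
  are not generated: in a pseudo-testcross map they are the less
  informative class and add nothing to what the scan's tests need to
  exercise.
* Bulk allele frequencies are binomial draws of $2 \times$ `bulk_size`
  allele copies around their expectation. Bulks of 20 individuals are the
  default because that is the bulk size of the motivating design; this
  finite-bulk binomial noise dominates the null variance of ED and must be
  present for realistic false-positive behaviour.
* At causal loci the early/late expectations are shifted apart by
  `causal_divergence` ($\pm d/2$, clipped to $[0,1]$). The default
  $d = 0.5$ models tight linkage to a locus under strong divergent
  selection (the bulk carrying the causal allele moves to 0.5, the other
  to 0). Divergence is flat across the causal unigene — without a linkage
  map, decay with distance is deliberately not modelled.
* Read depths are Poisson per pool per locus (default mean 50, a typical
  well-covered transcript), base calls multinomial on the true frequencies
  perturbed by a uniform per-read miscall rate (default 0.01).

The dataset is a deterministic function of `sim_config()` including its
seed: one `set.seed()` call with a fixed vectorized draw order. (A
consequence worth knowing: the substreams are not counter-based, so
changing `n_unigenes` or `loci_per_unigene` changes all downstream draws,
not just the inserted loci.)

`inject_filter_fodder()` overwrites chosen fractions of loci with the three
artefact classes the filters exist to remove (sub-threshold depth, bulk
alleles absent from both parents, exactly identical bulks) and relabels the
truth table, making filter recall and precision measurable quantities.

**What passing simulations do and do not show.** The generator reproduces
the statistical skeleton of a BSR-seq experiment — segregation, finite-bulk
sampling, Poisson depth, uniform miscalls. It does not model expression
variation across unigenes (depth is exchangeable across loci), allelic
expression bias, alignment or variant-calling artefacts, linkage decay, or
position-dependent error. Recovery rates measured on it validate the
pipeline's statistics, not the upstream read processing of real data.

## Problem sizes used by the test suite

The replicated experiments run at the design conditions of the motivating
study scaled to one causal unigene: 1,000 unigenes × 5 SNPs, bulks of 20,
mean depth 50, 1% error, divergence 0.5, with 100 replicate seeds for the
recovery and null-control experiments and 200 replicates for the smaller
Monte-Carlo separation checks. At these sizes the full suite completes in
about a minute on one core.

## Known limitations

* The enrichment test conditions on $K$ and treats loci as exchangeable;
  unigenes with unusually many SNPs are partially protected by $N$ entering
  the hypergeometric, but SNP-density artefacts (paralog collapse) will
  still inflate $Y$ and are not modelled.
* The ED threshold is a plain parameter. 0.74 is the conventional default
  here, not a quantity the package derives; users with different designs
  should inspect the ED distribution (`ed_records`) before trusting it.
* Single reference gene only in `ddct_relative_expression()`; geometric
  averaging over multiple reference genes is out of scope.
* The DEG screen applies thresholds to an existing differential-expression
  table; the underlying expression model (e.g. an empirical-Bayes count
  model) is deliberately not reimplemented.
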