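---
title: "Methods: CNV selection-signature scanning between trait-divergent groups"
author: "cnvselscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV selection-signature scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`cnvselscan` analyses a population callset of biallelic deletion copy-number
variants (CNVs) genotyped in a diploid cohort split into two trait-divergent
groups, labelled **HL** and **LL** (high and low litter size; any binary
contrast works the same way). The central container, `sv_set`, holds a
variant table (`chrom`, `pos`, `end`, `svtype`, signed `svlen`) and a
variant-by-sample dosage matrix with entries 0/1/2/`NA` counting copies of
the alternate (deletion) allele. Coordinates are 1-based inclusive, the VCF
and GFF3 native convention; BED input is converted at the boundary. For a
deletion, `end = pos + |svlen| - 1`, so the interval length equals `|svlen|`.

The pipeline stages are: population merging of per-individual calls →
quality control → sliding-window differentiation and diversity statistics →
dual-criterion outlier scan → candidate-locus filtering and gene annotation
→ cohort distribution statistics and GRM-based PCA. Each stage is an
exported function; `run_pipeline()` chains them and writes every
intermediate table plus a manifest, and the numbered scripts under
`analysis/` present the same chain as a narrated workflow.

# Population merging

Per-individual SV callers emit near-duplicate records for one physical
variant. `merge_population()` clusters records within each (chromosome, SV
type) stratum by **single linkage** under a two-part predicate:

* positional agreement — reciprocal overlap
  $\min(\text{shared}/L_a,\ \text{shared}/L_b)$ at least **0.5 for
  deletions** and **0.9 for insertions, inversions and duplications**.
  Insertions have no genomic span, so they instead require breakpoint
  distance ≤ 100 bp and a length ratio ≥ 0.9;
* genotype consistency — identical genotypes in at least **95%** of the
  samples called in both records (records with no comparable sample count
  as consistent).

All thresholds are inclusive. Single linkage matches common SV-merging
practice but is transitive: a chain A–B–C can place A and C in one cluster
even though their direct overlap is below threshold. This is documented
behaviour, and the cluster structure is verified in the tests against a
brute-force connected-components search. Each cluster is replaced by a
representative with the lower-median start and end (deterministic for even
cluster sizes), the per-sample majority genotype (ties become missing), and
the lexicographically smallest member id, which makes the merge idempotent
and invariant to input order.

# Quality control

Four filters run in a fixed order — variant length, excess heterozygosity,
missing rate, minor allele frequency — and each removed record is charged to
the *first* filter it fails, so the removal counts plus the survivor count
always reconcile with the input count. The bounds follow their printed
inequalities exactly: $|\mathrm{SVLEN}| \le 10{,}000{,}000$,
$P_\text{ExcHet} \ge 0.05$, $F_\text{MISSING} \le 0.2$ (a missing rate of
exactly 0.2 survives), $\mathrm{MAF} > 0$ (a monomorphic site is removed).
MAF and missingness are recomputed from genotypes rather than trusted from
INFO fields, which merging would have made stale.

`exc_het_pvalue()` is the one-sided exact Hardy–Weinberg test for
heterozygote **excess**: conditional on the allele counts, the heterozygote
count at a neutral site follows the exact HWE distribution, and the p-value
is $P(\text{het} \ge \text{observed})$, computed with the stable ratio
recurrence over compatible heterozygote counts. An all-heterozygote site in
10 samples gives $p = 1024/\binom{20}{10} \approx 0.0055$ and is removed; a
site with no heterozygotes can never show excess and returns 1. The test is
computed over the pooled cohort (QC precedes the group split) and plain
exact tail probabilities are used, not mid-p. The suite checks it against a
direct log-factorial enumeration for every genotype configuration with up
to 20 samples.

# Windowed selection statistics

Windows are 100 kb intervals advanced by 10 kb (defaults; both
configurable), starting at position 1 with trailing windows clipped at the
chromosome end. A CNV contributes to a window iff its **start breakpoint**
lies in the window — the per-site convention of windowed popgen tools;
spanning variants are not smeared across windows, which keeps window
statistics independent of variant length.

**FST.** Per site, the Weir–Cockerham (1984) variance components for two
diploid populations are computed from the group sample sizes, allele
frequencies and observed heterozygosities: $a$ (among populations), $b$
(among individuals within populations), $c$ (within individuals). The
window estimate is the weighted "ratio of sums" $\sum a / \sum (a+b+c)$,
robust to low-information sites. Sites where either group has no called
genotype, the pooled sample has fewer than two called individuals, or
$a+b+c=0$ (monomorphic) are unusable and skipped; windows with no usable
site carry `NA` and never rank. Per-site estimates can be negative (the
estimator is unbiased around zero); negative window values are retained in
the output and handled by the downstream exclusion rule.

**Diversity.** Per-site nucleotide diversity in a group with $n$ called
alleles and $k$ alternate copies is the exact mean pairwise difference
$2\frac{k}{n}\left(1-\frac{k}{n}\right)\frac{n}{n-1}$. Window diversity is
the sum over in-window sites divided by the window's **genomic span**
(clipped windows divide by their actual span), the standard windowed-π
definition, which makes the HL/LL ratio span-invariant. The contrast is
$\log_2(\pi_{HL}/\pi_{LL})$, defined only where both diversities are
positive; windows monomorphic in either group are excluded from ratio
ranking and counted in the logs.

# The dual-criterion scan

Candidate windows must lie simultaneously in the top 1% of windowed FST and
in the extreme 1% of the log2 diversity ratio (quantiles over
defined-statistic windows only; ties at the threshold are all included, so
the selected fraction never falls below the nominal one). The ratio tail
defaults to `both` with the mass split half per side, because a sweep in HL
depresses the ratio while a sweep in LL raises it and the direction is not
known a priori; when it is known — as in the bundled analysis, which plants
the sweep in HL — `ratio_tail = "lower"` concentrates the full 1% on the
informative side. Window-level intersection (rather than locus-level) was
chosen because both statistics are computed per window; loci inherit
selection from the windows containing their start breakpoint, deduplicated
across the overlapping windows of the sliding grid.

Final candidate filtering applies two exclusions: loci overlapping no gene
body (1 bp body overlap, no flank) and loci whose maximum
supporting-window FST is negative. Zero is not negative: an FST of exactly
0 survives. "FST" here is read as the supporting-window value because
selection operates at window level.

**A structural limitation worth stating plainly:** the diversity-ratio
criterion is blind to *completed, fixed differences*. If the deletion is
fixed in HL and absent in LL, every sweep site is monomorphic within both
groups, so $\pi_{HL} = \pi_{LL} = 0$, the ratio is undefined, and only the
FST criterion (which attains exactly 1 there) sees the region. The
intersection therefore cannot recover such a region, no matter how the
tails are configured — there is no within-group diversity signal left to
rank. The acceptance suite contains a deliberately failing check that
documents this regime. The scan performs as intended for the realistic
near-fixed case (e.g. HL frequency 0.98 against a polymorphic LL), where
the tests require at least 90% of fully-contained sweep windows to enter
the intersection.

# Feature annotation

`classify_features()` assigns each CNV exactly one category under the
precedence *exonic > splicing > UTR5 > UTR3 > ncRNA exonic > ncRNA intronic
> intronic > upstream/downstream > intergenic*, mirroring the documented
defaults of the common variant annotators: `exonic` means coding-sequence
overlap, `splicing` means overlap of a 2 bp intronic splice site without
touching any exon, flanks are 1 kb from the gene ends respecting strand,
and a variant inside both an upstream and a downstream flank (of the same
or neighbouring genes) takes the combined category. A CNV overlapping
several genes takes the highest-precedence category across them. Only
intergenic calls carry no gene id. The classifier is checked against an
independent brute-force classifier over random fixtures.

# Cohort statistics

* **Frequency spectra** use per-group alternate-allele frequencies over
  non-missing alleles (allele, not carrier, frequencies — the convention of
  the standard frequency tools), binned half-open in 0.1 steps with the
  last bin closed at 1. Per bin, a two-sided Fisher exact test compares
  in-bin versus out-of-bin counts between groups; bins empty in both groups
  get $p = 1$ by convention.
* **Chromosome distribution** is operationalised as one 2×2 test per
  chromosome — presence on versus off the chromosome by group, presence
  meaning at least one alternate allele in the group — with Yates
  continuity correction (configurable off) and Bonferroni correction by the
  number of chromosomes actually tested.
* **PCA** uses a VanRaden-style genetic relationship matrix: dosages
  mean-imputed at missing entries, centred by twice the allele frequency,
  cross-product scaled by $2\sum p(1-p)$ over polymorphic variants. Sample
  coordinates are eigenvectors scaled by the square roots of their
  eigenvalues, with the sign fixed so the largest-magnitude loading is
  positive (pure reproducibility convention).

# The cohort simulator

The simulator exists so every downstream stage is testable without raw
sequencing data. It emulates a genotyped deletion-CNV callset, not reads or
caller error models:

* **Differentiation** follows the Balding–Nichols model: ancestral
  frequencies from Beta(0.8, 0.8) truncated to [0.05, 0.95] (so the MAF
  filter is exercised but not dominant), and group frequencies drawn
  Beta$\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$, giving
  between-group variance $p(1-p)F$. With $F = 0$ the draw collapses to the
  ancestral frequency exactly. Genome-wide weighted Weir–Cockerham FST on
  simulated cohorts recovers the target within ±0.03 at targets from 0.01
  to 0.3 (tested over seeds).
* **Genotypes** are Hardy–Weinberg within groups; missingness is
  genotype-wise i.i.d. — the simplest mechanism that exercises the
  F\_MISSING filter. The default rates (15+15 samples, 5% missingness,
  background $F$ = 0.05) reflect a within-breed contrast cohort.
* **Positions** are uniform without overlap per chromosome; lengths are
  log-uniform on 1–100 kb by default, echoing real deletion-CNV length
  spectra with most mass at a few kb. Dense test fixtures (thousands of
  sites on a 10 Mb toy genome) use 0.5–1.5 kb lengths, since the
  non-overlap constraint cannot pack 5,000 variants of mean 21 kb into
  10 Mb; no genotype statistic depends on length.
* **Sweeps** are planted by overriding the group frequencies of every
  variant starting inside a configured region — a deterministic stand-in
  for directional selection, without linkage or haplotype structure.
* **Per-sample callsets** for merge testing duplicate each variant once per
  carrier, shift both breakpoints by one uniform offset in ±`jitter_bp`
  (capped at a quarter of the variant length, which guarantees that true
  duplicates always clear the 50% deletion threshold), and drop records
  i.i.d. Records keep the full population genotype vector — the state after
  cohort-wide re-genotyping, which the merge's concordance criterion
  requires. A length-preserving shift rather than independent breakpoint
  noise is used so that two jittered copies of a 10 kb deletion at ±100 bp
  always retain reciprocal overlap ≥ 0.98.
* Everything is deterministic under the config seed, with the caller's RNG
  state restored afterwards.

What passing tests on this simulator do **not** show about real data: no
linkage disequilibrium between CNVs, no caller-specific genotype error
structure, no population substructure beyond the two groups, no
informative missingness. Conclusions about estimator correctness transfer;
conclusions about real-data power do not.

# Numerical choices and degenerate inputs

* Quantile thresholds use R's default empirical quantile (type 7); all
  threshold comparisons are inclusive, and tie inclusion is preferred over
  exact-count truncation for determinism.
* Windows with identical statistic values throughout produce an empty
  selection with a warning rather than an arbitrary tail.
* `exc_het_pvalue` uses an upward ratio recurrence with rescaling, exact to
  numerical precision for cohort sizes far beyond the defaults.
* Degenerate inputs error early with informative messages: ancestral
  frequencies of exactly 0 or 1, sweeps outside the genome, zero-length
  intervals, panels missing a group, all-identical ranking statistics.
* Merge representatives use lower medians and lexicographic id choice so
  every tie-break is deterministic and order-free.
* Problem sizes in the tests — up to 5,000 sites × 30 samples per cohort,
  10 Mb toy genomes, 20-seed replicate loops — were chosen as the smallest
  sizes at which the stochastic assertions are stable.

# Known limitations

* π on a CNV genotype matrix is diversity *of the CNV markers*, not
  sequence diversity; the ratio scan inherits this interpretation.
* The fixed-difference blindness of the π-ratio criterion described above.
* Single-linkage merging can chain distinct nearby variants under heavy
  breakpoint noise; the thresholds, not the linkage rule, are the defence.
* The chromosome-distribution and bin tests treat variants as independent,
  which CNVs in strong LD would violate.
* BND/translocation records, non-diploid genotypes, and FORMAT fields
  beyond GT are out of scope.
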