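---
title: "Profiling immune-modulatory DNA motifs in gut metagenomes: methods and design"
author: "immunoMotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling immune-modulatory DNA motifs in gut metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoMotifs)
```

## The scientific problem

Bacterial genomic DNA carries short sequence motifs with opposing effects on
innate immunity. Unmethylated CpG motifs (consensus
purine–purine–CG–pyrimidine–pyrimidine) stimulate immune responses through
Toll-like receptor 9, while a small set of immunosuppressive motifs — the
telomere-derived TTAGGG and the 10-mer TCAAGCTTGA — counteract CpG-mediated
stimulation. Because gut bacteria differ in how many copies of these motifs
their genomes carry, the *composition* of a gut community translates into an
immune-modulatory genomic potential. Comparing that potential between
clinical groups (for example infants who later develop eczema and matched
healthy controls) requires a chain of standard metagenomic computations:
read preprocessing, exact motif counting with defensible strand conventions,
normalized abundance estimation, taxonomic attribution, diversity
estimation, and a differential-abundance test that is honest about small
sample sizes. `immunoMotifs` implements that chain as composable, tested
functions, together with a ground-truthed simulator so every stage can be
verified without any external download.

## Read preprocessing

Reads are quality-trimmed with the longest-qualifying-segment rule: the
retained fragment is the longest contiguous run of bases whose Phred
quality is at least the cutoff (default Q = 13), with ties broken by the
leftmost segment. The tie-break is a deliberate design choice — any
deterministic rule works, and leftmost is the simplest to reason about.
After trimming, reads shorter than 50 bases are dropped by default; the
floor is configurable (`trimReads(..., minLength = )`).

Host-derived reads are removed by screening reads against a host genome
with any external aligner and discarding every read with at least one hit
above 90% nucleotide identity and more than 50 aligned bases. The "50" is
interpreted as an absolute alignment length in bases, not a percentage,
because it is paired with a percent identity in the same rule; the
`hitFilter()` object makes either interpretation available. All threshold
comparisons in the package are strict (`>`), mirroring the "> X%"
convention in which such cutoffs are stated.

## Motif scanning conventions

Motif matching is exact over {A, C, G, T}; an N in a read never matches.
Three conventions needed fixing and are worth stating because they change
counts:

* **Overlaps count.** Occurrences, not non-overlapping tilings, are
  reported: `ATATAT` contains two occurrences of `ATAT`. This is the
  standard motif-count convention.
* **Both strands, palindromes once.** DNA is double-stranded, so both
  orientations are scanned by default. TCAAGCTTGA is its own reverse
  complement, which means its forward and reverse occurrences are the same
  physical sites; the scanner reports each such site exactly once. For
  non-palindromic motifs, reverse-strand occurrences are reported at their
  forward-strand coordinates with strand `"-"`.
* **Reads are the counting unit** for per-10^6-read rates (not read pairs).

Two occurrence statistics are derived from raw counts: copies per 10^6
reads (used for dataset-level motif profiles) and copies per 10^6 bases
(used for genome-level densities, where contig boundaries are never
spanned). Both recompute exactly from the raw count and the dataset size,
so they carry no hidden state.

The packaged motif set contains the two suppressive motifs and five
stimulatory CpG hexamers following the RRCGYY consensus. The stimulatory
entries are placeholders in the sense that any study would substitute its
own validated list; the set ships as a TSV (`readMotifSet()` /
`writeMotifSet()`) precisely so that replacing it is trivial.

## Abundance, coverage and attribution

Per-sequence abundance is expressed as normalized coverage: reads are
recruited to a target at > 95% identity and > 50% query-length coverage,
the lengths of all recruited reads are summed, divided by the target
length, and rescaled to a 10 Gb dataset
(`normCoverage = rawCoverage * 1e10 / datasetBases`). A read recruited by
several targets contributes to each of them, because per-sequence coverage
is defined independently per sequence; `recruitReads(uniqueBest = TRUE)`
provides the alternative single-best-target convention. Recruitment
coverage uses the trimmed read length (query length), which is also the
quantity summed into mapped bases.

Taxonomic and functional profiles use deterministic best-hit assignment:
highest bitscore, then highest identity, then lexicographically smallest
subject id. The tie-break chain matters only for reproducibility — it makes
profiles seed-free and invariant to row order of the hit table. Relative
abundances are percentages of *annotated* queries; unclassified queries are
reported separately rather than silently inflating a denominator.
Motif-bearing reads are attributed to taxa the same way, at > 80% identity
and > 50% query coverage.

## Diversity

Shannon diversity is reported in nats by default (the logarithm base is an
argument because published indices frequently omit it). Chao1 defaults to
the classic form `S_obs + F1^2 / (2 F2)` and falls back to the
bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when there are no
doubletons; the bias-corrected form can also be requested throughout, since
software packages differ in their default and the distinction is rarely
stated in papers. Rarefaction subsamples without replacement; the analytic
hypergeometric expectation (`expectedRichness()`) is exposed alongside the
Monte-Carlo curve both as a fast alternative and as the oracle the tests
compare against. Cross-sample comparisons rarefy every sample to a common
depth (7,000 sequences by default, a typical depth for marker-gene screens
of shotgun data).

## Differential abundance: the Metastats-style test

Counts are converted to within-sample proportions. Dense features get an
unequal-variance (Welch) t statistic on the proportions, with significance
from permutation of group labels: `p = (b + 1) / (B + 1)`, where `b` counts
permutations whose |t| reaches the observed |t| and `B` is the number of
permutations (default 1000). The `+1` correction keeps p-values strictly
positive and valid at any `B`. A feature whose pooled count is small in
*both* groups (below twice the per-group sample count, by default) is
"sparse": the t statistic is uninformative there, and the test switches to
a two-sided Fisher's exact test on the pooled 2x2 table of feature count
versus all-other count by group. Fold changes are ratios of group mean
proportions (group C over group E).

Numerical details that affect results: a zero numerator defines t = 0 even
when the variance is also zero (identical groups thus give p = 1); samples
are internally sorted by group and name before permuting, so column order
never changes the outcome; and the permutation stream is seeded explicitly,
making every result exactly reproducible. No multiple-testing correction is
applied by default because the raw-p convention at alpha = 0.05 is what
this analysis style reports; a Benjamini–Hochberg option exists
(`adjust = "BH"`).

The Mann-Whitney U test is exact — full enumeration of label arrangements
with midrank ties — whenever both groups have at most 10 observations, and
uses the tie-corrected normal approximation with continuity correction
otherwise. At 6 vs 6 the exact path always applies.

The Fig-4C-style association between a genus' relative abundance and its
contribution to a gene category is fit by closed-form OLS with Pearson
correlation and pointwise confidence bands; normality of the ratios can be
checked with a Jarque–Bera test implemented from sample skewness and
kurtosis.

## Genome bins

Bins from any external binner are screened by average identity to a
reference genome collection: a bin passes at > 95%. The average is
length-weighted over contigs by default — either weighting is defensible,
so the unweighted mean is available and the choice is explicit. Decontamination then removes individual contigs below 95%
identity; both operations are idempotent. Per-bin reports compute motif
densities only on contigs longer than 300 bases (short contigs carry
unstable density estimates) and compare per-sample normalized coverages
between groups with the exact Mann-Whitney test.

## The synthetic cohort generator

The generator exists so that every downstream estimate can be scored
against known truth. `makeGenome()` builds motif-controlled pseudo-genomes:
a uniform-random background is rejection-cleaned until it contains no
occurrence of any listed motif on either strand, then exactly
`round(density * length / 1e6)` copies are planted at non-overlapping,
buffer-separated positions. Half of the copies of non-palindromic motifs
are planted on the reverse strand to exercise strand logic; palindromic
motifs are planted forward only (their orientation is unobservable). The
generator rescans before returning, so realized content equals planted
content exactly.

`defaultCommunitySpec()` encodes the cohort the package is designed around:
two groups of six samples, eight genera at Escherichia-dominated
proportions typical of infant gut communities, 1 Mb pseudo-genomes, 250 bp
reads (a standard MiSeq read length), and a 0.5% per-base substitution
error rate. Two conditions are planted. The
Bifidobacterium genome carries 4 TCAAGCTTGA copies per 1e6 bases against 1
per 1e6 bases in the other genera, and its relative abundance is exactly
6-fold higher in group C (2/9 versus 1/27). Those two numbers are chosen so
that the *expected community-wide* TCAAGCTTGA density ratio between groups
is exactly 1.5 — the planted differential signal emerges from composition,
the way it would in real data, rather than from a per-group dial on the
motif density. TTAGGG is planted at equal density everywhere and therefore
serves as a built-in negative control.

Reads are drawn multinomially with probability proportional to abundance
times genome length, from uniform positions and strands; substitution
errors are injected per read at the stated rate, and each read's alignment
row is emitted from generator truth with identity
`100 * (1 - realized error fraction)`. Emitting alignments from truth
rather than running an aligner is deliberate: the pipeline consumes
standard tabular formats, so its tests should not depend on an aligner
binary or its version.

What the simulator does *not* emulate, and what passing tests therefore do
not establish about real data: within-read quality decay (qualities are
per-read constants drawn from N(mean, sd)); indels, chimeras and adapter
contamination; inter-sample overdispersion of community composition beyond
multinomial sampling (available for feature matrices via the Dirichlet
option, but not in the read simulator); GC bias; and strain-level variation
within a taxon. Results on real metagenomes additionally depend on aligner
sensitivity, reference completeness, and assembly quality, none of which
are modelled.

## Problem sizes and verification

The test suite verifies each operation against an independent oracle:
position-by-position scanning for the motif scanner (1,000 random
sequence/motif pairs), exhaustive segment search for the trimmer (1,000
random reads), hypergeometric enumeration for the Fisher path (200 random
tables), full label-arrangement enumeration for the Mann-Whitney test, the
analytic hypergeometric expectation for rarefaction, and 500 null
simulations (6 vs 6 samples, 50 features, depth 1e5) for permutation
p-value calibration, plus a 100-simulation power check on a planted 4-fold
feature. The end-to-end check runs the full pipeline on 20 independent
cohorts at 150,000 reads per sample — a "generous depth" chosen so that the
planted 1.5-fold motif difference corresponds to roughly a 2.8-standard-
deviation separation in per-sample motif counts, giving the 6-vs-6
comparison high power while keeping the whole suite inside a desktop-scale
run. These sizes are the package's own verification design; scaling any of
them up is a matter of changing one argument.

## Known limitations

* Motif matching is exact: IUPAC-degenerate motifs and position-weight
  matrices are out of scope.
* The trimmer implements one defensible reading of "trimmed at Q = 13";
  sliding-window or BWA-style trimmers will retain slightly different
  fragments.
* The Metastats-style test assumes exchangeability of samples under the
  null within each permutation; strongly structured covariates (batch,
  delivery mode) need stratified designs it does not provide.
* Fisher's sparse path tests pooled counts and therefore ignores
  between-sample variance for sparse features — the standard, and known,
  compromise for rare features.
* `chao1Richness` variance (and hence confidence intervals for richness)
  is not implemented; only point estimates are reported.
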