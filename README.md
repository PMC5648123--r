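# immunoMotifs

Comparative-metagenomics toolkit for profiling **immune-modulatory DNA
motifs** in shotgun metagenomes — immunostimulatory CpG motifs and the
immunosuppressive motifs TTAGGG and TCAAGCTTGA — and for testing whether
their abundance differs between clinical groups.

Bacterial DNA stimulates innate immunity through TLR-9 via unmethylated CpG
motifs (RRCGYY consensus); a small class of suppressive motifs counteracts
that stimulation. Because taxa differ in how many motif copies their genomes
carry, a gut community's composition implies an immune-modulatory genomic
potential. This package implements the full analysis chain used to compare
that potential between two groups of metagenomes (e.g. infants who develop
eczema versus matched healthy controls), for bioinformaticians working from
standard file formats (FASTA/FASTQ, BLAST tabular, SAM, TSV tables):

* **seq IO / preprocessing** — FASTA/FASTQ via Biostrings; quality trimming
  by the longest segment with all Phred ≥ Q (default Q = 13); host-read
  removal at > 90% identity and > 50 aligned bases (`trimReads`,
  `filterHostReads`).
* **motif profiling** — exact both-strand scanning with single counting of
  reverse-complement-palindromic sites (TCAAGCTTGA is its own reverse
  complement); occurrence rates per 10⁶ reads and per 10⁶ bases; per-genome
  motif densities; best-hit taxonomic attribution of motif-bearing reads
  (`scanMotifs`, `profileDataset`, `genomeMotifDensity`,
  `attributeMotifReads`).
* **abundance** — read recruitment at > 95% identity and > 50% query
  coverage; coverage normalized to 10 Gb
  (`norm = mappedBases / targetLength × 10¹⁰ / datasetBases`); taxon and
  functional-category relative-abundance profiles (`recruitReads`,
  `coverage`, `taxonProfile`, `functionProfile`).
* **community statistics** — Shannon and Chao1 diversity, analytic and
  Monte-Carlo rarefaction, a Metastats-style nonparametric test (Welch t on
  proportions, permutation p = (b+1)/(B+1), Fisher's exact path for sparse
  features), exact Mann-Whitney U, fold changes, OLS with confidence bands,
  Jarque-Bera (`metastatsTest`, `mannWhitneyTest`, `diversityEstimates`,
  `olsFit`).
* **genome screening** — bin screening at > 95% length-weighted average
  reference identity, contig decontamination, per-bin reports
  (`binScreen`, `decontaminateBin`, `binReport`).
* **synthetic data** — ground-truthed cohort simulator: motif-controlled
  pseudo-genomes, two groups of samples with reads, qualities and
  truth-derived alignment tables (`makeGenome`, `simulateSamples`,
  `simulateFeatureMatrix`).

## Worked example

Simulate the default two-group cohort (6 vs 6 samples, 8 genera, 50,000 ×
250 bp reads per sample). The Bifidobacterium pseudo-genome carries 4
TCAAGCTTGA copies per 10⁶ bases versus 1 elsewhere and is 6-fold more
abundant in group C, which makes the expected community-wide TCAAGCTTGA
density ratio exactly 1.5:

```r
library(immunoMotifs)

spec <- defaultCommunitySpec(seed = 7)
sim  <- simulateSamples(spec, withQualities = FALSE)

profs <- lapply(sim$reads, profileDataset,
                motifs = defaultMotifSet()[c("TCAAGCTTGA", "TTAGGG")])
rate <- sapply(profs, function(p) p$per1e6Reads[p$motif == "TCAAGCTTGA"])
round(rate, 1)
#>  C1  C2  C3  C4  C5  C6  E1  E2  E3  E4  E5  E6
#> 260 640 440 340 400 360 140 360 260 320 220 280

isC <- sim$group == "C"
mean(rate[isC]) / mean(rate[!isC])        # fold change, C over E
#> 1.54
mannWhitneyTest(rate[isC], rate[!isC])$p  # exact two-sided p
#> 0.0411
```

The motif is enriched about 1.5-fold in group C (its planted value) and the
difference is significant at α = 0.05. The Metastats-style permutation test
on the count matrix agrees:

```r
counts <- sapply(profs, function(p) p$count[p$motif == "TCAAGCTTGA"])
nReads <- sapply(sim$reads, length)
fm  <- featureMatrix(rbind(motif = counts, other = nReads - counts),
                     sim$group)
metastatsTest(fm, nPerm = 1000, seed = 8)[1, ]
#>   feature    meanC    meanE foldChange     p significant
#> 1   motif 0.000407 0.000263       1.54 0.025        TRUE
```

Genome coverage recovers the planted 6-fold abundance difference of the
focal genome:

```r
targets <- setNames(spec@genomeLength, paste0(spec@taxa, "_genome"))
cov <- sapply(sim$hits, function(h) {
  rec <- recruitReads(h)   # > 95% identity, > 50% query coverage
  coverage(targets, rec, sum(rec$queryLength))$normCoverage
})
rownames(cov) <- names(targets)
cres <- metastatsTest(cov, sim$group, nPerm = 1000, seed = 9)
cres[cres$feature == "Bifidobacterium_genome", ]
#>                  feature foldChange     p significant
#> 3 Bifidobacterium_genome       5.97 0.004        TRUE
```

`vignettes/immunoMotifs-methods.Rmd` documents the model, the conventions
(strand handling, strict thresholds, tie-breaks) and the simulator's design
in detail.

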