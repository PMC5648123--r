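#' Construct a CommunitySpec
#'
#' @param taxa character taxon names.
#' @param genomeLength pseudo-genome length per taxon (recycled).
#' @param motifDensity taxa x motifs matrix of planted copies per 1e6 bases
#'   (columns named by motif sequence), or a named vector for a single taxon
#'   set of motifs recycled across taxa.
#' @param abundanceC,abundanceE per-group taxon relative abundances (each
#'   summing to 1).
#' @param nPerGroup samples per group (default 6).
#' @param readsPerSample reads per sample (default 50000).
#' @param readLength read length in bases (default 250).
#' @param errorRate per-base substitution error rate (default 0.005).
#' @param qualMean,qualSd per-read Phred quality model (default 33, 3).
#' @param seed integer seed (mandatory).
#' @return A [CommunitySpec-class].
#' @seealso [defaultCommunitySpec()], [simulateSamples()]
#' @export
communitySpec <- function(taxa, genomeLength, motifDensity, abundanceC,
                          abundanceE, nPerGroup = 6, readsPerSample = 50000,
                          readLength = 250, errorRate = 0.005, qualMean = 33,
                          qualSd = 3, seed) {
  if (!is.matrix(motifDensity))
    motifDensity <- matrix(rep(motifDensity, each = length(taxa)),
                           nrow = length(taxa),
                           dimnames = list(taxa, names(motifDensity)))
  new("CommunitySpec", taxa = as.character(taxa),
      genomeLength = stats::setNames(rep_len(genomeLength, length(taxa)),
                                     taxa),
      motifDensity = motifDensity,
      abundance = matrix(c(abundanceC, abundanceE), ncol = 2,
                         dimnames = list(taxa, c("C", "E"))),
      nPerGroup = as.integer(nPerGroup),
      readsPerSample = as.integer(readsPerSample),
      readLength = as.integer(readLength), errorRate = errorRate,
      qualMean = qualMean, qualSd = qualSd, seed = as.integer(seed))
}

#' The default synthetic cohort
#'
#' Two groups of six samples emulating a case-control infant-gut cohort with
#' eight genera at roughly the proportions seen in such communities
#' (Escherichia-dominated, with Veillonella, Bifidobacterium, Klebsiella,
#' Enterobacter, Bacteroides, Clostridium, Enterococcus). Two conditions are
#' planted on 1 Mb pseudo-genomes:
#'
#' * the Bifidobacterium genome carries 4 TCAAGCTTGA copies per 1e6 bases
#'   against 1 per 1e6 bases elsewhere, and its relative abundance is exactly
#'   6-fold higher in group C (2/9 vs 1/27) — which makes the expected
#'   community-wide TCAAGCTTGA density ratio between groups exactly 1.5;
#' * every genome carries 2 TTAGGG copies per 1e6 bases, so that motif is
#'   exchangeable between groups.
#'
#' @param seed integer seed (mandatory).
#' @param nPerGroup,readsPerSample,readLength,errorRate passed through to
#'   [communitySpec()]; defaults 6, 50000, 250 bases, 0.005.
#' @return A [CommunitySpec-class].
#' @export
defaultCommunitySpec <- function(seed, nPerGroup = 6, readsPerSample = 50000,
                                 readLength = 250, errorRate = 0.005) {
  taxa <- c("Escherichia", "Veillonella", "Bifidobacterium", "Klebsiella",
            "Enterobacter", "Bacteroides", "Clostridium", "Enterococcus")
  abC <- c(0.30, 0.13, 2 / 9, 0.09, 0.08, 0.07, 0.06, 0)
  abC[8] <- 1 - sum(abC)
  abE <- c(0.38, 0.03, 1 / 27, 0.10, 0.11, 0.15, 0.09, 0)
  abE[8] <- 1 - sum(abE)
  dens <- cbind(TCAAGCTTGA = c(1, 1, 4, 1, 1, 1, 1, 1),
                TTAGGG = rep(2, 8))
  rownames(dens) <- taxa
  communitySpec(taxa, genomeLength = 1e6, motifDensity = dens,
                abundanceC = abC, abundanceE = abE, nPerGroup = nPerGroup,
                readsPerSample = readsPerSample, readLength = readLength,
                errorRate = errorRate, seed = seed)
}

#' Simulate a ground-truthed two-group metagenomic cohort
#'
#' Builds one motif-controlled pseudo-genome per taxon ([makeGenome()]), then
#' draws each sample's reads multinomially from the genomes with probability
#' proportional to group abundance times genome length, from uniform start
#' positions and random strands. Substitution errors are injected at the
#' specified per-base rate; each read's alignment row is emitted from the
#' generator's own truth with identity `100 * (1 - realized error fraction)`,
#' so the pipeline's standard-format consumers can be tested without running
#' an aligner. Everything is deterministic given the spec seed.
#'
#' @param spec a [CommunitySpec-class].
#' @param outDir optional directory; when given, writes per-sample FASTQ,
#'   genome FASTA, per-sample BLAST-tabular hit TSVs, a taxon map TSV and a
#'   truth JSON.
#' @param withQualities attach per-read Phred qualities (default TRUE; the
#'   quality model is a per-read mean drawn from N(qualMean, qualSd)).
#' @return list with `spec`, `genomes` (named `DNAStringSet`, one per
#'   taxon, subject ids `<taxon>_genome`), `planted` (per-taxon planted motif
#'   tables), `reads` (per-sample `QualityScaledDNAStringSet` or
#'   `DNAStringSet`), `hits` (per-sample canonical hit tables), `group`
#'   (named sample group labels), `taxonMap` (data.frame `subject`, `genus`),
#'   and `truth` (`composition`: taxa x samples read counts; `reads`:
#'   per-sample data.frames with source taxon, start, strand, error count).
#' @export
simulateSamples <- function(spec, outDir = NULL, withQualities = TRUE) {
  stopifnot(is(spec, "CommunitySpec"))
  motifs <- colnames(spec@motifDensity)
  L <- spec@readLength
  withSeed(spec@seed, {
    gens <- lapply(spec@taxa, function(tx)
      makeGenome(spec@genomeLength[[tx]], motifs,
                 spec@motifDensity[tx, ], seed = NULL,
                 name = paste0(tx, "_genome")))
    names(gens) <- spec@taxa
    genomes <- Biostrings::DNAStringSet(lapply(gens,
                                               function(g) g$genome[[1]]))
    names(genomes) <- paste0(spec@taxa, "_genome")
    planted <- lapply(gens, `[[`, "planted")

    genomesRc <- Biostrings::reverseComplement(genomes)
    samples <- c(paste0("C", seq_len(spec@nPerGroup)),
                 paste0("E", seq_len(spec@nPerGroup)))
    group <- stats::setNames(substr(samples, 1, 1), samples)
    glen <- spec@genomeLength[spec@taxa]
    composition <- matrix(0L, length(spec@taxa), length(samples),
                          dimnames = list(spec@taxa, samples))
    reads <- list(); hits <- list(); readTruth <- list()
    for (s in samples) {
      ab <- spec@abundance[, group[[s]]]
      prob <- ab * glen / sum(ab * glen)
      nTax <- as.integer(rmultinom(1, spec@readsPerSample, prob))
      composition[, s] <- nTax
      frags <- vector("list", length(spec@taxa))
      meta <- vector("list", length(spec@taxa))
      for (i in seq_along(spec@taxa)) {
        if (nTax[i] == 0L) next
        gl <- glen[[i]]
        starts <- sample.int(gl - L + 1L, nTax[i], replace = TRUE)
        strand <- sample(c("+", "-"), nTax[i], replace = TRUE)
        neg <- strand == "-"
        # forward reads first, then reverse-strand reads: a "-" read is the
        # matching window of the reverse-complement genome
        starts <- c(starts[!neg], starts[neg])
        nNeg <- sum(neg)
        sF <- starts[seq_len(nTax[i] - nNeg)]
        sR <- gl - starts[seq_len(nNeg) + nTax[i] - nNeg] - L + 2L
        frags[[i]] <- c(
          Biostrings::extractAt(genomes[[i]],
                                IRanges::IRanges(sF, width = L)),
          Biostrings::extractAt(genomesRc[[i]],
                                IRanges::IRanges(sR, width = L)))
        meta[[i]] <- data.frame(taxon = spec@taxa[i], start = starts,
                                strand = rep(c("+", "-"),
                                             c(nTax[i] - nNeg, nNeg)),
                                stringsAsFactors = FALSE)
      }
      frags <- do.call(c, frags[!vapply(frags, is.null, TRUE)])
      big <- unlist(frags)
      meta <- do.call(rbind, meta[!vapply(meta, is.null, TRUE)])
      n <- nrow(meta)
      ids <- paste0(s, "_r", seq_len(n))

      # substitution errors, injected on the concatenated sample sequence
      errN <- rbinom(n, L, spec@errorRate)
      realized <- integer(n)
      if (sum(errN) > 0) {
        readIdx <- rep.int(seq_len(n), errN)
        off <- sample.int(L, sum(errN), replace = TRUE)
        keep <- !duplicated((readIdx - 1) * as.double(L) + off)
        readIdx <- readIdx[keep]; off <- off[keep]
        realized <- tabulate(readIdx, nbins = n)
        gpos <- sort((readIdx - 1) * as.double(L) + off)
        cur <- as.character(Biostrings::extractAt(
          big, IRanges::IRanges(gpos, width = 1)))
        bases <- c("A", "C", "G", "T")
        newB <- bases[((match(cur, bases) - 1 +
          sample.int(3, length(gpos), replace = TRUE)) %% 4) + 1]
        big <- Biostrings::replaceLetterAt(big, gpos,
                                           paste(newB, collapse = ""))
      }
      frags <- Biostrings::DNAStringSet(big,
                                        start = (seq_len(n) - 1) *
                                          as.double(L) + 1,
                                        width = L)
      names(frags) <- ids

      if (withQualities) {
        q <- pmin(41L, pmax(2L, as.integer(round(
          rnorm(n, spec@qualMean, spec@qualSd)))))
        qchr <- rawToChar(as.raw(q + 33L), multiple = TRUE)
        frags <- Biostrings::QualityScaledDNAStringSet(
          frags, Biostrings::PhredQuality(strrep(qchr, L)))
      }
      reads[[s]] <- frags

      identity <- 100 * (1 - realized / L)
      h <- alignmentHits(ids, paste0(meta$taxon, "_genome"), identity,
                         alignLength = L, queryLength = L,
                         subjectStart = meta$start,
                         subjectEnd = meta$start + L - 1L,
                         evalue = 0, bitscore = round(2 * L * identity / 100,
                                                      1))
      h$strand <- meta$strand
      hits[[s]] <- h
      readTruth[[s]] <- cbind(data.frame(id = ids,
                                         stringsAsFactors = FALSE),
                              meta, errors = realized)
    }
    out <- list(spec = spec, genomes = genomes, planted = planted,
                reads = reads, hits = hits, group = group,
                taxonMap = data.frame(subject = paste0(spec@taxa, "_genome"),
                                      genus = spec@taxa,
                                      stringsAsFactors = FALSE),
                truth = list(composition = composition, reads = readTruth))
    if (!is.null(outDir)) writeSimulation(out, outDir)
    out
  })
}

# Write a simulated cohort to standard formats.
writeSimulation <- function(sim, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeSequences(sim$genomes, file.path(outDir, "genomes.fasta"))
  for (s in names(sim$reads)) {
    writeSequences(sim$reads[[s]], file.path(
      outDir, paste0(s, if (is(sim$reads[[s]], "QualityScaledDNAStringSet"))
        ".fastq" else ".fasta")))
    writeBlastTab(sim$hits[[s]], file.path(outDir, paste0(s, "_hits.tsv")))
  }
  utils::write.table(sim$taxonMap, file.path(outDir, "taxon_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(composition = sim$truth$composition,
                planted = sim$planted,
                group = as.list(sim$group))
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(outDir)
}

#' Simulate a feature-by-sample count matrix with planted fold changes
#'
#' Draws multinomial counts per sample (depth fixed) around group-specific
#' proportion vectors: group E uses equal base proportions, group C
#' multiplies the planted features' proportions by their fold and
#' renormalizes. With `dispersion > 0` each sample's proportions are first
#' drawn from a Dirichlet centred on the group vector with concentration
#' `1/dispersion` (overdispersed counts). With no planted features the two
#' groups are exchangeable (a null dataset).
#'
#' @param nFeatures number of features.
#' @param nPerGroup samples per group.
#' @param depth total count per sample.
#' @param planted named numeric of fold changes (C over E); names must be
#'   feature names `feature<i>`. NULL for a null dataset.
#' @param dispersion Dirichlet overdispersion (0 = pure multinomial).
#' @param seed integer seed (mandatory for reproducibility).
#' @return list with `se` (a [featureMatrix()] `SummarizedExperiment`) and
#'   `truth` (list `propC`, `propE`, `planted`).
#' @export
simulateFeatureMatrix <- function(nFeatures, nPerGroup, depth,
                                  planted = NULL, dispersion = 0, seed) {
  features <- paste0("feature", seq_len(nFeatures))
  propE <- stats::setNames(rep(1 / nFeatures, nFeatures), features)
  propC <- propE
  if (!is.null(planted)) {
    if (any(planted <= 0)) stop("planted folds must be > 0")
    idx <- match(names(planted), features)
    if (anyNA(idx)) stop("planted names must be feature names")
    propC[idx] <- propC[idx] * planted
    propC <- propC / sum(propC)
  }
  withSeed(seed, {
    drawGroup <- function(p, m) {
      vapply(seq_len(m), function(j) {
        pj <- if (dispersion > 0) {
          a <- rgamma(length(p), shape = p / dispersion)
          a / sum(a)
        } else p
        as.numeric(rmultinom(1, depth, pj))
      }, numeric(nFeatures))
    }
    counts <- cbind(drawGroup(propC, nPerGroup), drawGroup(propE, nPerGroup))
    rownames(counts) <- features
    colnames(counts) <- c(paste0("C", seq_len(nPerGroup)),
                          paste0("E", seq_len(nPerGroup)))
    list(se = featureMatrix(counts, rep(c("C", "E"), each = nPerGroup)),
         truth = list(propC = propC, propE = propE,
                      planted = planted %||% stats::setNames(numeric(0),
                                                             character(0))))
  })
}
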