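#' Read or write a motif set TSV
#'
#' Tab-separated with header columns `name`, `sequence`, `class`. The packaged
#' default set is user-replaceable through this format.
#'
#' @param path path to the TSV.
#' @return [readMotifSet()] returns a [MotifSet-class]; [writeMotifSet()]
#'   returns `path` invisibly.
#' @export
readMotifSet <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  motifSet(tab$name, tab$sequence, tab$class)
}

#' @rdname readMotifSet
#' @param motifs a [MotifSet-class].
#' @export
writeMotifSet <- function(motifs, path) {
  utils::write.table(
    data.frame(name = names(motifs), sequence = unname(motifSequences(motifs)),
               class = unname(immunoClass(motifs))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged immune-modulatory motif set
#'
#' Seven motifs: five stimulatory CpG hexamers following the RRCGYY
#' (purine-purine-CG-pyrimidine-pyrimidine) consensus of immunostimulatory
#' CpG oligonucleotides, plus the two immunosuppressive motifs TTAGGG and
#' TCAAGCTTGA. The stimulatory entries are configurable placeholders — any
#' study-specific set can be supplied as a TSV via [readMotifSet()].
#'
#' @return A [MotifSet-class] of 7 motifs.
#' @examples
#' defaultMotifSet()
#' @export
defaultMotifSet <- function() {
  readMotifSet(system.file("extdata", "immunomodulatory_motifs.tsv",
                           package = "immunoMotifs", mustWork = TRUE))
}

#' Scan sequences for exact motif occurrences
#'
#' Reports every occurrence (overlapping occurrences included) of each motif
#' in each sequence. With `bothStrands = TRUE`, reverse-complement occurrences
#' are reported at their forward-strand coordinates with strand `"-"`; for
#' motifs that are their own reverse complement (e.g. TCAAGCTTGA) each
#' physical site is reported exactly once, on the forward strand. Matching is
#' exact over {A,C,G,T}: an N in the sequence never matches.
#'
#' Positions are 1-based starts on the forward strand.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param motifs a [MotifSet-class], or one/more motif strings.
#' @param bothStrands scan both strands (default TRUE).
#' @return data.frame with columns `seqId`, `motif` (name), `start` (1-based),
#'   `strand`.
#' @seealso [profileDataset()], [genomeMotifDensity()]
#' @export
scanMotifs <- function(seqs, motifs, bothStrands = TRUE) {
  seqs <- asDNAStringSet(seqs)
  motifs <- asMotifSet(motifs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  out <- vector("list", 2L * length(motifs))
  k <- 0L
  for (i in seq_along(motifs)) {
    mseq <- motifSequences(motifs)[i]
    mname <- names(motifs)[i]
    m <- Biostrings::vmatchPattern(mseq, seqs, fixed = TRUE)
    st <- unlist(IRanges::start(m), use.names = FALSE)
    nhit <- lengths(m)
    k <- k + 1L
    out[[k]] <- data.frame(seqId = rep(ids, nhit),
                           motif = rep(mname, length(st)),
                           start = st, strand = rep("+", length(st)),
                           stringsAsFactors = FALSE)
    if (bothStrands && !isRcPalindrome(mseq)) {
      mrc <- Biostrings::vmatchPattern(revComp(mseq), seqs, fixed = TRUE)
      st <- unlist(IRanges::start(mrc), use.names = FALSE)
      nhit <- lengths(mrc)
      k <- k + 1L
      out[[k]] <- data.frame(seqId = rep(ids, nhit),
                             motif = rep(mname, length(st)),
                             start = st, strand = rep("-", length(st)),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(match(res$seqId, ids), match(res$motif, names(motifs)),
                   res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Total occurrence count per motif over a sequence set, both-strand with
# palindrome deduplication (fast path used by the profilers).
countMotifTotals <- function(seqs, motifs, bothStrands = TRUE) {
  seqs <- asDNAStringSet(seqs)
  motifs <- asMotifSet(motifs)
  vapply(seq_along(motifs), function(i) {
    mseq <- motifSequences(motifs)[[i]]
    n <- sum(Biostrings::vcountPattern(mseq, seqs, fixed = TRUE))
    if (bothStrands && !isRcPalindrome(mseq))
      n <- n + sum(Biostrings::vcountPattern(revComp(mseq), seqs,
                                             fixed = TRUE))
    as.numeric(n)
  }, numeric(1)) |> stats::setNames(names(motifs))
}

# Per-sequence occurrence counts for one motif (both-strand, palindrome
# deduplicated); used to flag motif-bearing reads without materializing hits.
countMotifPerSequence <- function(seqs, motif, bothStrands = TRUE) {
  seqs <- asDNAStringSet(seqs)
  motif <- toupper(motif)
  n <- Biostrings::vcountPattern(motif, seqs, fixed = TRUE)
  if (bothStrands && !isRcPalindrome(motif))
    n <- n + Biostrings::vcountPattern(revComp(motif), seqs, fixed = TRUE)
  stats::setNames(as.numeric(n), names(seqs))
}

#' Motif occurrence statistics for a read set
#'
#' Counts every motif over all reads (both strands, palindromes counted once)
#' and derives the two occurrence rates reported for metagenomes: copies per
#' 1e6 reads and copies per 1e6 bases. Reads are expected to be preprocessed
#' (quality-trimmed and host-filtered).
#'
#' @param reads a `DNAStringSet`/`QualityScaledDNAStringSet` (or character).
#' @param motifs a [MotifSet-class] (default [defaultMotifSet()]).
#' @param bothStrands scan both strands (default TRUE).
#' @return data.frame with one row per motif: `motif`, `class`, `count`,
#'   `per1e6Reads`, `per1e6Bases`, `nReads`, `nBases`.
#' @export
profileDataset <- function(reads, motifs = defaultMotifSet(),
                           bothStrands = TRUE) {
  reads <- asDNAStringSet(reads)
  if (length(reads) == 0L)
    stop("empty dataset: occurrence rates are undefined")
  motifs <- asMotifSet(motifs)
  nReads <- length(reads)
  nBases <- sum(as.numeric(Biostrings::width(reads)))
  counts <- countMotifTotals(reads, motifs, bothStrands)
  data.frame(motif = names(motifs), class = unname(immunoClass(motifs)),
             count = unname(counts),
             per1e6Reads = unname(counts) * 1e6 / nReads,
             per1e6Bases = unname(counts) * 1e6 / nBases,
             nReads = nReads, nBases = nBases,
             stringsAsFactors = FALSE)
}

#' Motif density of a genome
#'
#' Both-strand, palindrome-deduplicated occurrence count per 1e6 bases over a
#' (possibly multi-contig) genome. Contig boundaries are never spanned.
#'
#' @param genome a `DNAStringSet` of contigs (or character vector / single
#'   string).
#' @param motifs a [MotifSet-class] or motif string(s).
#' @param bothStrands scan both strands (default TRUE).
#' @return named numeric: copies per 1e6 bases, one entry per motif.
#' @examples
#' genomeMotifDensity(strrep("A", 1e4), "TTAGGG")  # 0
#' @export
genomeMotifDensity <- function(genome, motifs, bothStrands = TRUE) {
  genome <- asDNAStringSet(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  nBases <- sum(as.numeric(Biostrings::width(genome)))
  counts <- countMotifTotals(genome, asMotifSet(motifs), bothStrands)
  counts * 1e6 / nBases
}

#' Attribute motif-bearing reads to taxa
#'
#' Each motif-bearing read is assigned to the taxon of its best passing hit
#' (highest bitscore, then highest identity, then lexicographically smallest
#' subject id); reads without a passing hit — or whose best subject is absent
#' from the taxon map — are reported as `"unclassified"`. Fractions sum to 1
#' over assigned plus unclassified reads.
#'
#' @param motifReadIds character ids of the motif-bearing reads.
#' @param hits a canonical hit table covering (a subset of) those reads.
#' @param filter a [HitFilter-class]; the reference screen uses > 80% identity
#'   and > 50% query length coverage.
#' @param taxonMap named character vector (or data.frame with columns
#'   `subject`, `taxon`) mapping subject ids to taxa.
#' @return data.frame with columns `taxon`, `nReads`, `fraction`, sorted by
#'   decreasing fraction with `"unclassified"` last.
#' @export
attributeMotifReads <- function(motifReadIds, hits,
                                filter = hitFilter(minIdentity = 80,
                                                   minQueryCov = 0.5),
                                taxonMap) {
  if (is.data.frame(taxonMap))
    taxonMap <- stats::setNames(as.character(taxonMap$taxon),
                                taxonMap$subject)
  motifReadIds <- unique(as.character(motifReadIds))
  if (length(motifReadIds) == 0L)
    return(data.frame(taxon = character(), nReads = numeric(),
                      fraction = numeric()))
  h <- hits[hits$query %in% motifReadIds, , drop = FALSE]
  h <- h[hitsPass(h, filter), , drop = FALSE]
  best <- bestHits(h)
  taxon <- unname(taxonMap[best$subject])
  assigned <- stats::setNames(ifelse(is.na(taxon), "unclassified", taxon),
                              best$query)
  full <- assigned[motifReadIds]
  full[is.na(full)] <- "unclassified"
  tab <- table(full)
  out <- data.frame(taxon = names(tab), nReads = as.numeric(tab),
                    fraction = as.numeric(tab) / length(full),
                    stringsAsFactors = FALSE)
  uncl <- out$taxon == "unclassified"
  out <- rbind(out[!uncl, , drop = FALSE][order(-out$fraction[!uncl]), ],
               out[uncl, , drop = FALSE])
  rownames(out) <- NULL
  out
}

# Coercions shared by the scanning functions.
asDNAStringSet <- function(x) {
  if (is(x, "QualityScaledDNAStringSet")) as(x, "DNAStringSet")
  else if (is(x, "DNAStringSet")) x
  else if (is(x, "DNAString")) Biostrings::DNAStringSet(list(x))
  else Biostrings::DNAStringSet(x)
}

asMotifSet <- function(x) {
  if (is(x, "MotifSet")) return(x)
  x <- toupper(as.character(x))
  nm <- names(x)
  if (is.null(nm)) nm <- x
  motifSet(nm, x, rep("unspecified", length(x)))
}
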