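#' Read sequences from FASTA or FASTQ
#'
#' FASTA files yield a [Biostrings::DNAStringSet]; FASTQ files yield a
#' [Biostrings::QualityScaledDNAStringSet] with Phred(+33) qualities. Records
#' are returned in file order; multi-line FASTA is folded.
#'
#' @param path path to the sequence file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return A `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (FASTQ).
#' @seealso [writeSequences()]
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq")
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  else
    Biostrings::readDNAStringSet(path, format = "fasta")
}

#' Write sequences to FASTA or FASTQ
#'
#' A `QualityScaledDNAStringSet` is written as FASTQ (Phred+33), anything else
#' as FASTA.
#'
#' @param x a `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(x, path) {
  if (is(x, "QualityScaledDNAStringSet"))
    Biostrings::writeQualityScaledXStringSet(x, path)
  else
    Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

# Longest contiguous run of positions with quality >= cutoff; leftmost on
# ties. Returns c(start, length); length 0 if no position qualifies.
longestQualitySegment <- function(quals, qCutoff) {
  if (length(quals) == 0L) return(c(1L, 0L))
  r <- rle(quals >= qCutoff)
  if (!any(r$values)) return(c(1L, 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(starts[best], r$lengths[best])
}

#' Quality-trim a single read
#'
#' Returns the longest contiguous segment in which every base has Phred
#' quality at least `qCutoff` (leftmost segment on ties), or an empty read if
#' no base qualifies. This is the longest-qualifying-segment rule used for
#' read preprocessing at Q = 13.
#'
#' @param bases DNA string of the read.
#' @param quals integer Phred scores, one per base.
#' @param qCutoff minimum Phred quality (default 13).
#' @return list with elements `bases` and `quals` for the trimmed segment
#'   (both empty when nothing qualifies).
#' @examples
#' trimRead("ACGTACGT", c(30, 30, 5, 30, 30, 30, 5, 30), qCutoff = 13)
#' @export
trimRead <- function(bases, quals, qCutoff = 13) {
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop("bases and quals must have equal length")
  if (qCutoff < 0) stop("qCutoff must be >= 0")
  seg <- longestQualitySegment(quals, qCutoff)
  if (seg[2L] == 0L) return(list(bases = "", quals = integer()))
  list(bases = substr(bases, seg[1L], seg[1L] + seg[2L] - 1L),
       quals = quals[seq.int(seg[1L], length.out = seg[2L])])
}

#' Quality-trim a set of reads
#'
#' Applies the longest-qualifying-segment rule ([trimRead()]) to every read
#' and drops reads whose trimmed length falls below `minLength` (default 50
#' bases, the post-trim read-length floor; set 0 to keep everything,
#' including width-0 reads).
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param qCutoff minimum Phred quality (default 13).
#' @param minLength minimum post-trim read length in bases (default 50).
#' @return A trimmed `QualityScaledDNAStringSet` (possibly with fewer reads).
#' @export
trimReads <- function(reads, qCutoff = 13, minLength = 50) {
  if (!is(reads, "QualityScaledDNAStringSet"))
    stop("reads must be a QualityScaledDNAStringSet")
  if (length(reads) == 0L) return(reads)
  ql <- as(Biostrings::quality(reads), "IntegerList")
  segs <- vapply(ql, longestQualitySegment, integer(2), qCutoff = qCutoff)
  keep <- if (minLength > 0) segs[2L, ] >= minLength else rep(TRUE, ncol(segs))
  starts <- segs[1L, keep]
  widths <- segs[2L, keep]
  sq <- IRanges::narrow(as(reads[keep], "DNAStringSet"),
                        start = starts, width = widths)
  qq <- IRanges::narrow(as(Biostrings::quality(reads)[keep], "BStringSet"),
                        start = starts, width = widths)
  Biostrings::QualityScaledDNAStringSet(sq, Biostrings::PhredQuality(qq))
}

#' Remove host-derived reads using alignment hits
#'
#' A read is discarded iff at least one of its hits against the host genome
#' passes the filter (default: > 90% nucleotide identity and > 50 aligned
#' bases). The partition is exact and order-preserving. Hits referencing read
#' ids not present in `reads` are ignored with a warning giving their count.
#'
#' @param reads a `DNAStringSet` or `QualityScaledDNAStringSet` with read ids
#'   as names.
#' @param hits an alignment hit table ([alignmentHits()] layout).
#' @param filter a [HitFilter-class]; default `hitFilter(90, minAlignLength =
#'   50)`.
#' @return list with `kept` (the reads that survive, in input order) and
#'   `discardedIds` (character vector of removed read ids).
#' @export
filterHostReads <- function(reads, hits,
                            filter = hitFilter(minIdentity = 90,
                                               minAlignLength = 50)) {
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be named by read id")
  if (nrow(hits)) {
    unknown <- !(hits$query %in% ids)
    if (any(unknown))
      warning(sum(unknown), " hit(s) reference read ids not in the input")
    hits <- hits[!unknown, , drop = FALSE]
  }
  pass <- if (nrow(hits)) hitsPass(hits, filter) else logical(0)
  discard <- unique(hits$query[pass])
  list(kept = reads[!(ids %in% discard)], discardedIds = discard)
}

#' Summarize a read set
#'
#' @param reads a `DNAStringSet`/`QualityScaledDNAStringSet` (or anything with
#'   `Biostrings::width()`).
#' @return list with `nReads`, `nBases` and `meanLength` (NaN when empty).
#' @export
datasetSummary <- function(reads) {
  w <- as.numeric(Biostrings::width(reads))
  list(nReads = length(w), nBases = sum(w),
       meanLength = if (length(w)) mean(w) else NaN)
}
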