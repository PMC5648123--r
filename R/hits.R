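#' Build a canonical alignment hit table
#'
#' The pipeline is aligner-agnostic: all identity/coverage screens operate on
#' a plain data.frame of hits with canonical columns. Coordinates are 1-based
#' inclusive (BLAST tabular convention); reversed subject coordinates are
#' normalized (`subjectStart <= subjectEnd`) with the strand recorded as "-".
#'
#' @param query,subject character ids.
#' @param identity percent identity in (0, 100].
#' @param alignLength alignment length in bases (>= 1).
#' @param queryLength query (read) length in bases, NA when unknown.
#' @param subjectStart,subjectEnd 1-based inclusive subject coordinates.
#' @param evalue,bitscore optional alignment scores.
#' @return data.frame with columns `query`, `subject`, `identity`,
#'   `alignLength`, `queryLength`, `subjectStart`, `subjectEnd`, `strand`,
#'   `evalue`, `bitscore`.
#' @export
alignmentHits <- function(query, subject, identity, alignLength,
                          queryLength = NA, subjectStart = NA,
                          subjectEnd = NA, evalue = NA, bitscore = NA) {
  n <- length(query)
  df <- data.frame(query = as.character(query),
                   subject = as.character(subject),
                   identity = as.numeric(identity),
                   alignLength = as.numeric(alignLength),
                   queryLength = rep_len(as.numeric(queryLength), n),
                   subjectStart = rep_len(as.numeric(subjectStart), n),
                   subjectEnd = rep_len(as.numeric(subjectEnd), n),
                   strand = rep_len("+", n),
                   evalue = rep_len(as.numeric(evalue), n),
                   bitscore = rep_len(as.numeric(bitscore), n),
                   stringsAsFactors = FALSE)
  rev <- !is.na(df$subjectStart) & !is.na(df$subjectEnd) &
    df$subjectStart > df$subjectEnd
  if (any(rev)) {
    tmp <- df$subjectStart[rev]
    df$subjectStart[rev] <- df$subjectEnd[rev]
    df$subjectEnd[rev] <- tmp
    df$strand[rev] <- "-"
  }
  if (any(df$identity <= 0 | df$identity > 100, na.rm = TRUE))
    stop("identity must be in (0, 100]")
  if (any(df$alignLength < 1, na.rm = TRUE))
    stop("alignLength must be >= 1")
  df
}

#' Read a 12-column BLAST tabular (outfmt 6) hit file
#'
#' Expects the standard column order qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore. Query lengths are not part
#' of the format; supply them via `queryLengths` when a downstream filter
#' needs query coverage.
#'
#' @param path path to the tabular file (no header).
#' @param queryLengths optional named numeric vector of read lengths, indexed
#'   by query id.
#' @return A canonical hit table (see [alignmentHits()]).
#' @export
readBlastTab <- function(path, queryLengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          rep("numeric", 10)))
  ql <- if (is.null(queryLengths)) NA
        else unname(queryLengths[tab$qseqid])
  alignmentHits(tab$qseqid, tab$sseqid, tab$pident, tab$length,
                queryLength = ql, subjectStart = tab$sstart,
                subjectEnd = tab$send, evalue = tab$evalue,
                bitscore = tab$bitscore)
}

#' Write a canonical hit table as BLAST tabular (outfmt 6)
#'
#' Mismatch and gap-open counts are not tracked by the canonical table and are
#' written as 0.
#'
#' @param hits a canonical hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlastTab <- function(hits, path) {
  sstart <- ifelse(hits$strand == "-", hits$subjectEnd, hits$subjectStart)
  send <- ifelse(hits$strand == "-", hits$subjectStart, hits$subjectEnd)
  out <- data.frame(hits$query, hits$subject, hits$identity,
                    hits$alignLength, 0L, 0L, 1L, hits$alignLength,
                    sstart, send,
                    ifelse(is.na(hits$evalue), 0, hits$evalue),
                    ifelse(is.na(hits$bitscore), 0, hits$bitscore))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read alignment hits from a SAM file
#'
#' Mapped records are converted to the canonical hit layout: alignment length
#' is the aligned reference width from the CIGAR, and percent identity is
#' computed from the NM (edit distance) tag when present, otherwise NA.
#' Unmapped records are skipped.
#'
#' @param path path to a SAM (`.sam`, converted internally) or BAM file.
#' @return A canonical hit table (see [alignmentHits()]).
#' @export
readSamHits <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "strand", "qwidth", "mapq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(Rsamtools::BamFile(path), param = p)[[1]]
  if (length(b$qname) == 0L) {
    return(alignmentHits(character(), character(), numeric(), numeric()))
  }
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  alnw <- GenomicAlignments::cigarWidthAlongQuerySpace(
    b$cigar, after.soft.clipping = TRUE)
  nm <- b$tag$NM
  ident <- if (is.null(nm)) rep(NA_real_, length(b$qname))
           else 100 * (1 - nm / pmax(alnw, 1))
  hits <- alignmentHits(b$qname, as.character(b$rname),
                        ifelse(is.na(ident), 100, ident), refw,
                        queryLength = b$qwidth, subjectStart = b$pos,
                        subjectEnd = b$pos + refw - 1,
                        bitscore = as.numeric(b$mapq))
  hits$identity[is.na(ident)] <- NA_real_
  hits$strand <- as.character(b$strand)
  hits
}

#' Apply a HitFilter to a hit table
#'
#' All comparisons are strict (`>`), matching the "> X% identity", "> 50%
#' query length coverage" conventions. Query coverage is
#' `alignLength / queryLength`; a set `minQueryCov` with missing query lengths
#' is an error. Target coverage needs a `targetLength` column on the hits.
#'
#' @param hits a canonical hit table.
#' @param filter a [HitFilter-class].
#' @return logical vector, TRUE where the hit passes every set threshold.
#' @export
hitsPass <- function(hits, filter) {
  stopifnot(is(filter, "HitFilter"))
  pass <- rep(TRUE, nrow(hits))
  if (!is.na(filter@minIdentity))
    pass <- pass & !is.na(hits$identity) & hits$identity > filter@minIdentity
  if (!is.na(filter@minAlignLength))
    pass <- pass & hits$alignLength > filter@minAlignLength
  if (!is.na(filter@minQueryCov)) {
    if (any(is.na(hits$queryLength[pass])))
      stop("query lengths are required for a query-coverage threshold")
    pass <- pass & (hits$alignLength / hits$queryLength) > filter@minQueryCov
  }
  if (!is.na(filter@minTargetCov)) {
    if (is.null(hits$targetLength))
      stop("hits need a 'targetLength' column for a target-coverage threshold")
    cov <- (hits$subjectEnd - hits$subjectStart + 1) / hits$targetLength
    pass <- pass & !is.na(cov) & cov > filter@minTargetCov
  }
  pass
}

#' Best hit per query
#'
#' Deterministic best-hit selection used for taxonomic and functional
#' attribution: highest bitscore, then highest identity, then lexicographically
#' smallest subject id. Missing bitscores rank below any present bitscore.
#'
#' @param hits a canonical hit table (usually already filtered).
#' @return One row per distinct query, in order of first appearance.
#' @export
bestHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  bs <- ifelse(is.na(hits$bitscore), -Inf, hits$bitscore)
  o <- order(match(hits$query, unique(hits$query)), -bs, -hits$identity,
             hits$subject)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query), , drop = FALSE]
}
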