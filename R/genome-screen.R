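#' Assign best reference identities to bin contigs from a hit table
#'
#' Builds a [GenomeBin-class] from contig sequences and a contig-vs-reference
#' hit table: each contig gets the identity of its best hit (bitscore, then
#' identity, then lexicographic subject); contigs with no hit score 0.
#'
#' @param binId bin identifier.
#' @param contigs a `DNAStringSet` (or named character vector) of contigs.
#' @param hits canonical hit table with contig ids as queries.
#' @return A [GenomeBin-class].
#' @export
binFromHits <- function(binId, contigs, hits) {
  if (!is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  best <- bestHits(hits)
  ident <- stats::setNames(best$identity, best$query)[names(contigs)]
  ident[is.na(ident)] <- 0
  genomeBin(binId, contigs, unname(ident))
}

#' Screen genome bins by average reference identity
#'
#' Keeps bins whose average genome identity against the reference collection
#' exceeds the threshold (default > 95%, the post-binning screen). The
#' average is length-weighted over contigs by default; an unweighted mean is
#' available since either convention is defensible.
#'
#' @param bins list of [GenomeBin-class] objects.
#' @param minAvgIdentity percent threshold a bin's average must exceed
#'   (strict; default 95).
#' @param weighted length-weight the per-contig identities (default TRUE).
#' @return list with `pass` (the passing bins) and `report` (data.frame
#'   `binId`, `nContigs`, `totalLength`, `avgIdentity`, `pass`).
#' @export
binScreen <- function(bins, minAvgIdentity = 95, weighted = TRUE) {
  if (length(bins) == 0L) stop("no bins supplied")
  report <- do.call(rbind, lapply(bins, function(b) {
    if (length(b) == 0L) stop("empty bin '", binId(b), "'")
    ai <- avgIdentity(b, weighted = weighted)
    data.frame(binId = binId(b), nContigs = length(b),
               totalLength = totalLength(b), avgIdentity = ai,
               pass = ai > minAvgIdentity, stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  list(pass = bins[report$pass], report = report)
}

#' Remove low-identity contigs from a bin
#'
#' Contigs strictly below the identity threshold (default 95%) are excluded —
#' the decontamination step that removes likely mis-assigned contigs. The
#' operation is idempotent.
#'
#' @param bin a [GenomeBin-class].
#' @param threshold percent identity below which a contig is removed
#'   (default 95).
#' @return list with `bin` (the cleaned [GenomeBin-class]), `removed`
#'   (character ids of excluded contigs) and `empty` (TRUE when nothing
#'   survives).
#' @export
decontaminateBin <- function(bin, threshold = 95) {
  keep <- contigIdentity(bin) >= threshold
  cleaned <- genomeBin(binId(bin), contigs(bin)[keep],
                       contigIdentity(bin)[keep])
  list(bin = cleaned, removed = names(contigs(bin))[!keep],
       empty = !any(keep))
}

#' Per-bin summary report
#'
#' One row per bin: size, contig count, average identity, motif densities
#' (copies per 1e6 bases, computed on contigs longer than `minContigLength`,
#' default 300 bases — short contigs are not counted), and, when per-sample
#' normalized coverages with group labels are supplied, the between-group
#' coverage fold change (group C over group E mean) with a Mann-Whitney
#' two-sided p-value.
#'
#' @param bin a [GenomeBin-class].
#' @param motifs a [MotifSet-class] or motif string(s); default the packaged
#'   suppressive motifs.
#' @param sampleCoverage optional named numeric of per-sample normalized
#'   coverages for this bin.
#' @param group optional group labels parallel to `sampleCoverage` (first
#'   unique value = group C).
#' @param minContigLength contigs at or below this length are excluded from
#'   density computation (default 300).
#' @param alpha significance threshold for the coverage comparison.
#' @return One-row data.frame: `binId`, `nContigs`, `totalLength`,
#'   `avgIdentity`, `density.<motif>` columns, and (with coverage)
#'   `coverageFoldChange`, `coverageP`, `significant`.
#' @export
binReport <- function(bin, motifs = defaultMotifSet()[c("TTAGGG",
                                                        "TCAAGCTTGA")],
                      sampleCoverage = NULL, group = NULL,
                      minContigLength = 300, alpha = 0.05) {
  motifs <- asMotifSet(motifs)
  ctg <- contigs(bin)
  long <- ctg[Biostrings::width(ctg) > minContigLength]
  dens <- if (length(long)) genomeMotifDensity(long, motifs)
          else stats::setNames(rep(NA_real_, length(motifs)), names(motifs))
  out <- data.frame(binId = binId(bin), nContigs = length(bin),
                    totalLength = totalLength(bin),
                    avgIdentity = avgIdentity(bin),
                    stringsAsFactors = FALSE)
  for (m in names(dens)) out[[paste0("density.", m)]] <- dens[[m]]
  if (!is.null(sampleCoverage)) {
    if (is.null(group) || length(group) != length(sampleCoverage))
      stop("group labels parallel to sampleCoverage are required")
    lev <- unique(as.character(group))
    cc <- sampleCoverage[group == lev[1]]
    ce <- sampleCoverage[group == lev[2]]
    mw <- mannWhitneyTest(cc, ce)
    out$coverageFoldChange <- mean(cc) / mean(ce)
    out$coverageP <- mw$p
    out$significant <- mw$p < alpha
  }
  out
}
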