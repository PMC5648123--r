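#' @export
setGeneric("motifSequences", function(x) standardGeneric("motifSequences"))

#' @export
setGeneric("immunoClass", function(x) standardGeneric("immunoClass"))

#' @export
setGeneric("binId", function(x) standardGeneric("binId"))

#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @export
setGeneric("contigIdentity", function(x) standardGeneric("contigIdentity"))

#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @export
setGeneric("avgIdentity", function(x, ...) standardGeneric("avgIdentity"))

#' Named sets of exact immune-modulatory DNA motifs
#'
#' A `MotifSet` holds short exact DNA motifs together with their immunological
#' class: `"stimulatory"` for CpG-type motifs that activate innate immunity via
#' TLR-9, `"suppressive"` for motifs (such as TTAGGG and TCAAGCTTGA) that
#' counteract CpG-mediated stimulation.
#'
#' @slot name character, unique motif names.
#' @slot sequence character, exact motifs over {A,C,G,T}, length >= 4.
#' @slot immunoClass character, one of `"stimulatory"` or `"suppressive"`.
#'
#' @seealso [motifSet()], [defaultMotifSet()], [scanMotifs()]
#' @export
setClass("MotifSet",
  representation(name = "character", sequence = "character",
                 immunoClass = "character"))

setValidity("MotifSet", function(object) {
  msg <- character()
  n <- length(object@name)
  if (length(object@sequence) != n || length(object@immunoClass) != n)
    msg <- c(msg, "slots 'name', 'sequence' and 'immunoClass' must be parallel")
  if (any(!nzchar(object@name)) || anyDuplicated(object@name))
    msg <- c(msg, "motif names must be nonempty and unique")
  if (any(grepl("[^ACGT]", object@sequence)))
    msg <- c(msg, "motif sequences must be over {A,C,G,T}")
  if (any(nchar(object@sequence) < 4L))
    msg <- c(msg, "motif sequences must be at least 4 bases long")
  if (!all(object@immunoClass %in% c("stimulatory", "suppressive",
                                     "unspecified")))
    msg <- c(msg, "immunoClass must be 'stimulatory', 'suppressive' or 'unspecified'")
  if (length(msg)) msg else TRUE
})

#' Construct a MotifSet
#'
#' @param name character vector of unique motif names.
#' @param sequence character vector of exact DNA motifs (A/C/G/T only).
#' @param immunoClass character vector, `"stimulatory"` or `"suppressive"`.
#' @return A [MotifSet-class] object.
#' @examples
#' motifSet(c("tcaagcttga", "ttaggg"),
#'          c("TCAAGCTTGA", "TTAGGG"),
#'          c("suppressive", "suppressive"))
#' @export
motifSet <- function(name, sequence, immunoClass) {
  new("MotifSet", name = as.character(name),
      sequence = toupper(as.character(sequence)),
      immunoClass = as.character(immunoClass))
}

#' @describeIn MotifSet-class number of motifs.
#' @param x a `MotifSet`.
#' @export
setMethod("length", "MotifSet", function(x) length(x@name))

#' @describeIn MotifSet-class motif names.
#' @export
setMethod("names", "MotifSet", function(x) x@name)

#' @describeIn MotifSet-class motif sequences, named by motif name.
#' @export
setMethod("motifSequences", "MotifSet",
  function(x) stats::setNames(x@sequence, x@name))

#' @describeIn MotifSet-class immunological classes, named by motif name.
#' @export
setMethod("immunoClass", "MotifSet",
  function(x) stats::setNames(x@immunoClass, x@name))

#' @describeIn MotifSet-class subset by index or name.
#' @param i index or motif name.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MotifSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@name)
  new("MotifSet", name = x@name[i], sequence = x@sequence[i],
      immunoClass = x@immunoClass[i])
})

setMethod("show", "MotifSet", function(object) {
  cat("MotifSet with", length(object), "motifs\n")
  print(data.frame(name = object@name, sequence = object@sequence,
                   class = object@immunoClass, row.names = NULL))
})

#' Identity/coverage thresholds for alignment hits
#'
#' Encodes the BLAST-style cutoffs used throughout the pipeline, e.g. host-read
#' removal at > 90% nucleotide identity and > 50 aligned bases, read
#' recruitment at > 95% identity and > 50% query length coverage, or protein
#' best-hit annotation at > 40% identity and > 50% query coverage. All
#' comparisons are strict (`>`), mirroring the "> X%" convention. Thresholds
#' left `NA` are not applied; at least one must be set.
#'
#' @slot minIdentity percent identity threshold in (0, 100], or NA.
#' @slot minQueryCov fraction of query length that must be aligned, in (0, 1],
#'   or NA.
#' @slot minAlignLength minimum alignment length in bases, or NA.
#' @slot minTargetCov fraction of the target region that must be covered, in
#'   (0, 1], or NA.
#' @seealso [hitFilter()], [hitsPass()]
#' @export
setClass("HitFilter",
  representation(minIdentity = "numeric", minQueryCov = "numeric",
                 minAlignLength = "numeric", minTargetCov = "numeric"),
  prototype(minIdentity = NA_real_, minQueryCov = NA_real_,
            minAlignLength = NA_real_, minTargetCov = NA_real_))

setValidity("HitFilter", function(object) {
  msg <- character()
  chk1 <- function(v) length(v) == 1L
  if (!chk1(object@minIdentity) || !chk1(object@minQueryCov) ||
      !chk1(object@minAlignLength) || !chk1(object@minTargetCov))
    msg <- c(msg, "all thresholds must be length-1")
  if (!is.na(object@minIdentity) &&
      (object@minIdentity <= 0 || object@minIdentity > 100))
    msg <- c(msg, "minIdentity must be in (0, 100]")
  if (!is.na(object@minQueryCov) &&
      (object@minQueryCov <= 0 || object@minQueryCov > 1))
    msg <- c(msg, "minQueryCov must be a fraction in (0, 1]")
  if (!is.na(object@minAlignLength) && object@minAlignLength < 1)
    msg <- c(msg, "minAlignLength must be >= 1")
  if (!is.na(object@minTargetCov) &&
      (object@minTargetCov <= 0 || object@minTargetCov > 1))
    msg <- c(msg, "minTargetCov must be a fraction in (0, 1]")
  if (is.na(object@minIdentity) && is.na(object@minQueryCov) &&
      is.na(object@minAlignLength) && is.na(object@minTargetCov))
    msg <- c(msg, "at least one threshold must be set")
  if (length(msg)) msg else TRUE
})

#' Construct a HitFilter
#'
#' @param minIdentity percent identity a hit must exceed (strict), or NA.
#' @param minQueryCov fraction of query length a hit must exceed (strict),
#'   or NA.
#' @param minAlignLength alignment length in bases a hit must exceed (strict),
#'   or NA.
#' @param minTargetCov fraction of the target region a hit must exceed
#'   (strict), or NA.
#' @return A [HitFilter-class] object.
#' @examples
#' hostFilter <- hitFilter(minIdentity = 90, minAlignLength = 50)
#' recruitFilter <- hitFilter(minIdentity = 95, minQueryCov = 0.5)
#' @export
hitFilter <- function(minIdentity = NA, minQueryCov = NA,
                      minAlignLength = NA, minTargetCov = NA) {
  new("HitFilter", minIdentity = as.numeric(minIdentity),
      minQueryCov = as.numeric(minQueryCov),
      minAlignLength = as.numeric(minAlignLength),
      minTargetCov = as.numeric(minTargetCov))
}

setMethod("show", "HitFilter", function(object) {
  fmt <- function(v, unit) if (is.na(v)) "-" else paste0("> ", v, unit)
  cat("HitFilter: identity ", fmt(object@minIdentity, "%"),
      ", query cov ", fmt(object@minQueryCov, ""),
      ", align length ", fmt(object@minAlignLength, " bp"),
      ", target cov ", fmt(object@minTargetCov, ""), "\n", sep = "")
})

#' A genome bin with per-contig reference identities
#'
#' A set of assembled contigs attributed to one organism, annotated with each
#' contig's best percent identity against a reference genome collection
#' (contigs with no hit score 0). Used by the post-binning screen that keeps
#' bins above 95% average genome identity and by contig-level decontamination.
#'
#' @slot binId single bin identifier.
#' @slot contigs a [Biostrings::DNAStringSet] of contig sequences.
#' @slot contigIdentity numeric, best reference identity (%) per contig,
#'   parallel to `contigs`.
#' @seealso [genomeBin()], [binScreen()], [decontaminateBin()]
#' @export
setClass("GenomeBin",
  representation(binId = "character", contigs = "DNAStringSet",
                 contigIdentity = "numeric"))

setValidity("GenomeBin", function(object) {
  msg <- character()
  if (length(object@binId) != 1L || !nzchar(object@binId))
    msg <- c(msg, "binId must be a single nonempty string")
  if (length(object@contigIdentity) != length(object@contigs))
    msg <- c(msg, "contigIdentity must be parallel to contigs")
  if (length(object@contigIdentity) &&
      (any(object@contigIdentity < 0) || any(object@contigIdentity > 100)))
    msg <- c(msg, "contig identities must be in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeBin
#'
#' @param binId single bin identifier.
#' @param contigs a [Biostrings::DNAStringSet] (or named character vector) of
#'   contig sequences.
#' @param contigIdentity best reference identity (%) per contig; contigs
#'   without a hit should be given 0.
#' @return A [GenomeBin-class] object.
#' @export
genomeBin <- function(binId, contigs, contigIdentity) {
  if (!is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  new("GenomeBin", binId = as.character(binId), contigs = contigs,
      contigIdentity = as.numeric(contigIdentity))
}

#' @describeIn GenomeBin-class bin identifier.
#' @param x a `GenomeBin`.
#' @export
setMethod("binId", "GenomeBin", function(x) x@binId)

#' @describeIn GenomeBin-class contig sequences.
#' @export
setMethod("contigs", "GenomeBin", function(x) x@contigs)

#' @describeIn GenomeBin-class per-contig best reference identities (%).
#' @export
setMethod("contigIdentity", "GenomeBin", function(x) x@contigIdentity)

#' @describeIn GenomeBin-class number of contigs.
#' @export
setMethod("length", "GenomeBin", function(x) length(x@contigs))

#' @describeIn GenomeBin-class total bin length in bases.
#' @export
setMethod("totalLength", "GenomeBin",
  function(x) sum(as.numeric(Biostrings::width(x@contigs))))

#' Average genome identity of a bin
#'
#' Length-weighted (default) or unweighted mean of per-contig best reference
#' identities. The screen keeps bins whose average exceeds 95%.
#'
#' @param x a [GenomeBin-class].
#' @param weighted weight contigs by their length (default) or equally.
#' @param ... ignored.
#' @return Average identity in percent.
#' @export
setMethod("avgIdentity", "GenomeBin", function(x, weighted = TRUE, ...) {
  if (length(x) == 0L) stop("empty bin: average identity undefined")
  if (weighted)
    stats::weighted.mean(x@contigIdentity, Biostrings::width(x@contigs))
  else
    mean(x@contigIdentity)
})

setMethod("show", "GenomeBin", function(object) {
  cat("GenomeBin '", object@binId, "': ", length(object), " contigs, ",
      totalLength(object), " bp, avg identity ",
      if (length(object)) round(avgIdentity(object), 2) else NA, "%\n",
      sep = "")
})

#' Parameters of a synthetic two-group metagenomic cohort
#'
#' Describes the ground-truthed communities emulating a case-control infant
#' gut cohort: per-taxon pseudo-genome lengths and planted motif densities,
#' per-group taxon relative abundances, sample sizes, read length, per-base
#' substitution error rate, and a per-read Phred quality model. The seed is
#' mandatory so every simulated artifact is reproducible.
#'
#' @slot taxa character, taxon (genus) names.
#' @slot genomeLength named numeric, pseudo-genome length per taxon (bases).
#' @slot motifDensity numeric matrix taxa x motifs, planted copies per 1e6
#'   bases (motif columns named by motif sequence).
#' @slot abundance numeric matrix taxa x groups (columns "C", "E"), relative
#'   abundances summing to 1 per group.
#' @slot nPerGroup samples per group.
#' @slot readsPerSample reads per sample.
#' @slot readLength read length (bases).
#' @slot errorRate per-base substitution error rate.
#' @slot qualMean,qualSd per-read mean Phred quality model.
#' @slot seed integer seed.
#' @seealso [communitySpec()], [defaultCommunitySpec()], [simulateSamples()]
#' @export
setClass("CommunitySpec",
  representation(taxa = "character", genomeLength = "numeric",
                 motifDensity = "matrix", abundance = "matrix",
                 nPerGroup = "integer", readsPerSample = "integer",
                 readLength = "integer", errorRate = "numeric",
                 qualMean = "numeric", qualSd = "numeric", seed = "integer"))

setValidity("CommunitySpec", function(object) {
  msg <- character()
  nt <- length(object@taxa)
  if (nt == 0L || anyDuplicated(object@taxa))
    msg <- c(msg, "taxa must be nonempty and unique")
  if (length(object@genomeLength) != nt || any(object@genomeLength < 1000))
    msg <- c(msg, "one genomeLength >= 1000 required per taxon")
  if (nrow(object@motifDensity) != nt || is.null(colnames(object@motifDensity)))
    msg <- c(msg, "motifDensity must have one row per taxon and named motif columns")
  if (any(object@motifDensity < 0))
    msg <- c(msg, "motif densities must be >= 0")
  if (!identical(colnames(object@abundance), c("C", "E")) ||
      nrow(object@abundance) != nt)
    msg <- c(msg, "abundance must be a taxa x c('C','E') matrix")
  else if (any(abs(colSums(object@abundance) - 1) > 1e-8) ||
           any(object@abundance < 0))
    msg <- c(msg, "abundances must be nonnegative and sum to 1 per group")
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (object@readsPerSample < 1L) msg <- c(msg, "readsPerSample must be >= 1")
  if (object@readLength < 20L) msg <- c(msg, "readLength must be >= 20")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a single integer seed is mandatory")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec: ", length(object@taxa), " taxa, ",
      object@nPerGroup, "+", object@nPerGroup, " samples, ",
      object@readsPerSample, " reads/sample x ", object@readLength,
      " bp, error rate ", object@errorRate, ", seed ", object@seed, "\n",
      sep = "")
  ab <- data.frame(taxon = object@taxa,
                   genomeLength = object@genomeLength,
                   C = object@abundance[, "C"], E = object@abundance[, "E"],
                   row.names = NULL)
  print(cbind(ab, object@motifDensity))
})
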