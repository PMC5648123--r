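#' Generate a pseudo-genome with planted motif copies
#'
#' Draws a uniform-random background sequence, scrubs it until it contains no
#' occurrence of any listed motif on either strand (rejection cleaning: one
#' base inside every spurious occurrence is resampled and the scan repeated),
#' then plants exactly `round(density * length / 1e6)` copies of each motif
#' at non-overlapping positions. For non-reverse-complement-palindromic
#' motifs, alternate copies are inserted on the reverse strand to exercise
#' strand logic; palindromic motifs are planted forward only. The realized
#' occurrence count of each listed motif therefore equals the planted count
#' exactly, which the generator verifies by rescanning before returning.
#'
#' @param length genome length in bases.
#' @param motifs a [MotifSet-class] or motif string(s) whose content is
#'   controlled.
#' @param density copies per 1e6 bases per motif (recycled / matched by motif
#'   name).
#' @param seed optional integer seed.
#' @param name sequence name for the output.
#' @return list with `genome` (a length-1 named `DNAStringSet`), `planted`
#'   (data.frame `motif`, `start`, `strand`, 1-based forward-strand starts)
#'   and `nCopies` (named planted copy counts).
#' @examples
#' g <- makeGenome(10000, "TCAAGCTTGA", density = 300, seed = 1)
#' genomeMotifDensity(g$genome, "TCAAGCTTGA")  # 300
#' @export
makeGenome <- function(length, motifs, density, seed = NULL,
                       name = "synthetic_genome") {
  motifs <- asMotifSet(motifs)
  mseqs <- motifSequences(motifs)
  density <- rep_len(as.numeric(density), length(motifs))
  nCopies <- stats::setNames(as.integer(round(density * length / 1e6)),
                             names(motifs))
  lens <- nchar(mseqs)
  maxLen <- max(lens)
  buffer <- maxLen
  if (sum(nCopies * (lens + 2 * buffer)) > 0.5 * length)
    stop("infeasible motif density for this genome length")
  withSeed(seed, {
    for (attempt in 1:5) {
      g <- buildCleanBackground(length, mseqs)
      planted <- plantMotifs(g, mseqs, nCopies, buffer)
      gset <- Biostrings::DNAStringSet(planted$genome)
      names(gset) <- name
      realized <- countMotifTotals(gset, motifs, bothStrands = TRUE)
      if (all(realized == nCopies)) {
        return(list(genome = gset, planted = planted$planted,
                    nCopies = nCopies))
      }
    }
    stop("could not realize the requested motif content; ",
         "motifs may overlap each other")
  })
}

# Uniform background with zero occurrences of any pattern (both strands).
buildCleanBackground <- function(length, mseqs) {
  bases <- c("A", "C", "G", "T")
  g <- Biostrings::DNAString(
    rawToChar(charToRaw("ACGT")[sample.int(4L, length, replace = TRUE)]))
  pats <- unique(c(mseqs, vapply(mseqs, revComp, "")))
  for (iter in 1:50) {
    pos <- integer()
    for (p in pats) {
      m <- Biostrings::matchPattern(p, g, fixed = TRUE)
      if (base::length(m))
        pos <- c(pos, IRanges::start(m) + nchar(p) %/% 2L)
    }
    if (!base::length(pos)) return(g)
    pos <- unique(pos)
    g <- Biostrings::replaceLetterAt(
      g, pos, paste(sample(bases, base::length(pos), replace = TRUE),
                    collapse = ""))
  }
  stop("background cleaning did not converge")
}

# Plant copies at stratified non-overlapping positions: the genome is split
# into one block per copy and each copy lands uniformly inside its block,
# guaranteeing non-overlap with margin `buffer`.
plantMotifs <- function(g, mseqs, nCopies, buffer) {
  total <- sum(nCopies)
  gc <- as.character(g)
  L <- nchar(gc)
  if (total == 0L)
    return(list(genome = g,
                planted = data.frame(motif = character(), start = integer(),
                                     strand = character())))
  block <- L %/% total
  maxLen <- max(nchar(mseqs))
  if (block < maxLen + 2 * buffer + 1)
    stop("infeasible motif density for this genome length")
  order <- sample(rep(names(nCopies), nCopies))
  starts <- integer(total)
  strands <- character(total)
  for (k in seq_len(total)) {
    mname <- order[k]
    mlen <- nchar(mseqs[[mname]])
    lo <- (k - 1L) * block + 1L + buffer
    hi <- k * block - mlen - buffer
    st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    pal <- isRcPalindrome(mseqs[[mname]])
    fwd <- pal || (sum(order[seq_len(k)] == mname) %% 2L == 1L)
    ins <- if (fwd) mseqs[[mname]] else revComp(mseqs[[mname]])
    substr(gc, st, st + mlen - 1L) <- ins
    starts[k] <- st
    strands[k] <- if (fwd) "+" else "-"
  }
  list(genome = Biostrings::DNAString(gc),
       planted = data.frame(motif = order, start = starts, strand = strands,
                            stringsAsFactors = FALSE))
}
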