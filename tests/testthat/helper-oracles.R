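# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately takes a different computational route than the
# package implementation it checks.

# Naive position-by-position motif scan (forward strand).
naiveScanForward <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (m > n) return(integer())
  starts <- seq_len(n - m + 1L)
  starts[substring(seq, starts, starts + m - 1L) == motif]
}

# Naive both-strand scan with palindrome deduplication; returns total count.
naiveScanCount <- function(seq, motif, bothStrands = TRUE) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  n <- length(naiveScanForward(seq, motif))
  if (bothStrands && !identical(motif, rc))
    n <- n + length(naiveScanForward(seq, rc))
  n
}

# Exhaustive longest-qualifying-segment search over all O(n^2) contiguous
# segments, via prefix counts of failing positions (no rle): segment [i, j]
# is clean iff no failing position lies inside it.
bruteTrim <- function(quals, cutoff) {
  n <- length(quals)
  if (n == 0L) return(c(start = 1L, len = 0L))
  bad <- cumsum(quals < cutoff)
  bad0 <- c(0L, bad[-n])
  clean <- outer(bad0, bad, function(bi, bj) bj - bi == 0L)
  lenM <- outer(seq_len(n), seq_len(n), function(i, j) j - i + 1L)
  lenM[!clean | lenM < 1L] <- 0L
  m <- max(lenM)
  if (m == 0L) return(c(start = 1L, len = 0L))
  hit <- which(lenM == m, arr.ind = TRUE)
  c(start = min(hit[, "row"]), len = m)
}

# Two-sided Fisher's exact p for a 2x2 table by hypergeometric enumeration:
# sum of all dhyper probabilities <= the observed one (within tolerance).
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of label arrangements,
# with U computed by direct pairwise comparison (not rank sums).
mwOracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  uOf <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  uObs <- uOf(x, y)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

randomDNA <- function(n, withN = FALSE) {
  alph <- if (withN) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, n, replace = TRUE), collapse = "")
}

randomMotif <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A small QualityScaledDNAStringSet built from explicit quality vectors.
makeQualReads <- function(bases, quals, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(bases))
  qstr <- vapply(quals, function(q)
    rawToChar(as.raw(as.integer(q) + 33L)), "")
  r <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(bases), Biostrings::PhredQuality(qstr))
  names(r) <- ids
  r
}

qualInts <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}
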