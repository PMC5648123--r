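test_that("motif sets validate and load from TSV", {
  ms <- defaultMotifSet()
  expect_equal(length(ms), 7L)
  expect_setequal(unique(unname(immunoClass(ms))),
                  c("stimulatory", "suppressive"))
  expect_equal(unname(motifSequences(ms)["TCAAGCTTGA"]), "TCAAGCTTGA")
  expect_error(motifSet("bad", "ACGX", "suppressive"), "A,C,G,T")
  expect_error(motifSet(c("a", "a"), c("ACGT", "AACC"),
                        rep("suppressive", 2)), "unique")
  tf <- tempfile(fileext = ".tsv")
  writeMotifSet(ms, tf)
  expect_equal(motifSequences(readMotifSet(tf)), motifSequences(ms))
})

test_that("scanMotifs reports exact, overlapping, stranded occurrences", {
  hit <- scanMotifs(c(s = "TCAAGCTTGA"), "TCAAGCTTGA")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 1L)
  two <- scanMotifs(c(s = "TTAGGGTTAGGG"), "TTAGGG", bothStrands = FALSE)
  expect_equal(two$start, c(1L, 7L))
  # overlapping occurrences are counted
  ov <- scanMotifs(c(s = "ATATATAT"), "ATAT", bothStrands = FALSE)
  expect_equal(ov$start, c(1L, 3L, 5L))
  # reverse-strand occurrence at forward coordinates
  rc <- scanMotifs(c(s = paste0("CC", "CCCTAA", "GG")), "TTAGGG")
  expect_equal(rc$start, 3L)
  expect_equal(rc$strand, "-")
  # N never matches
  expect_equal(nrow(scanMotifs(c(s = "TTANGG"), "TTAGGG")), 0L)
})

test_that("palindromic motifs are counted once per physical site", {
  expect_true(isRcPalindrome("TCAAGCTTGA"))
  expect_false(isRcPalindrome("TTAGGG"))
  set.seed(11)
  for (i in 1:25) {
    s <- c(x = randomDNA(3000))
    fwd <- nrow(scanMotifs(s, "TCAAGCTTGA", bothStrands = FALSE))
    both <- nrow(scanMotifs(s, "TCAAGCTTGA", bothStrands = TRUE))
    expect_equal(both, fwd)
  }
})

test_that("scanMotifs equals the naive oracle and is strand-symmetric", {
  set.seed(22)
  for (i in 1:100) {
    s <- randomDNA(sample(200:3000, 1), withN = i %% 5 == 0)
    motif <- randomMotif(sample(4:10, 1))
    got <- scanMotifs(c(x = s), motif, bothStrands = FALSE)
    expect_equal(got$start, naiveScanForward(s, motif))
    both <- nrow(scanMotifs(c(x = s), motif, bothStrands = TRUE))
    expect_equal(both, naiveScanCount(s, motif))
    # symmetry: both-strand count invariant under reverse complement
    srr <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(nrow(scanMotifs(c(x = srr), motif, bothStrands = TRUE)),
                 both)
  }
})

test_that("profileDataset rates derive exactly from counts", {
  reads <- Biostrings::DNAStringSet(c(r1 = "TCAAGCTTGAAAAA",
                                      r2 = strrep("A", 14),
                                      r3 = "TTAGGGAATTAGGG",
                                      r4 = strrep("C", 8)))
  prof <- profileDataset(reads, defaultMotifSet()[c("TTAGGG", "TCAAGCTTGA")])
  expect_equal(prof$count, c(2, 1))
  expect_equal(prof$per1e6Reads, c(2, 1) * 1e6 / 4)
  expect_equal(prof$per1e6Bases, c(2, 1) * 1e6 / 50)
  expect_error(profileDataset(Biostrings::DNAStringSet()), "empty")
  # zero hits give zero rates
  z <- profileDataset(Biostrings::DNAStringSet(c(a = strrep("A", 100))),
                      defaultMotifSet()["TCAAGCTTGA"])
  expect_equal(z$per1e6Reads, 0)
})

test_that("profiles are invariant to read order and chunking", {
  set.seed(33)
  reads <- Biostrings::DNAStringSet(
    setNames(vapply(rep(500, 40), randomDNA, ""), paste0("r", 1:40)))
  ms <- defaultMotifSet()
  p1 <- profileDataset(reads, ms)
  p2 <- profileDataset(reads[sample(40)], ms)
  expect_equal(p1$count, p2$count)
  expect_equal(p1$per1e6Bases, p2$per1e6Bases)
  # chunked counting sums to the same totals
  c1 <- profileDataset(reads[1:17], ms)$count +
    profileDataset(reads[18:40], ms)$count
  expect_equal(c1, p1$count)
})

test_that("genome motif density counts both strands and respects contigs", {
  g <- makeGenome(1e6, "TCAAGCTTGA", density = 5, seed = 91)
  expect_equal(unname(genomeMotifDensity(g$genome, "TCAAGCTTGA")), 5)
  # a motif split across a contig boundary is never counted
  halves <- Biostrings::DNAStringSet(c(c1 = paste0(strrep("A", 20), "TCAAG"),
                                       c2 = paste0("CTTGA", strrep("A", 20))))
  expect_equal(unname(genomeMotifDensity(halves, "TCAAGCTTGA")), 0)
  joined <- Biostrings::DNAStringSet(
    c(j = paste0(strrep("A", 20), "TCAAGCTTGA", strrep("A", 20))))
  expect_equal(unname(genomeMotifDensity(joined, "TCAAGCTTGA")), 1e6 / 50)
})

test_that("motif-bearing reads are attributed by best passing hit", {
  f <- hitFilter(minIdentity = 80, minQueryCov = 0.5)
  tm <- data.frame(subject = c("g1", "g2"),
                   taxon = c("Bifidobacterium", "Escherichia"))
  ids <- paste0("r", 1:4)
  one <- alignmentHits(ids, "g1", 95, 90, queryLength = 100, bitscore = 100)
  a <- attributeMotifReads(ids, one, f, tm)
  expect_equal(a$taxon, "Bifidobacterium")
  expect_equal(a$fraction, 1)
  # no passing hits: everything unclassified
  low <- alignmentHits(ids, "g1", 50, 90, queryLength = 100, bitscore = 100)
  b <- attributeMotifReads(ids, low, f, tm)
  expect_equal(b$taxon, "unclassified")
  expect_equal(b$fraction, 1)
  # mixed attribution sums to one, unclassified reported last
  mix <- alignmentHits(c("r1", "r2", "r3"), c("g1", "g2", "gX"),
                       c(95, 95, 95), 90, queryLength = 100, bitscore = 100)
  m <- attributeMotifReads(ids, mix, f, tm)
  expect_equal(sum(m$fraction), 1)
  expect_equal(m$taxon[nrow(m)], "unclassified")
  expect_equal(m$nReads[m$taxon == "unclassified"], 2)  # r3 unmapped taxon, r4 no hit
})
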