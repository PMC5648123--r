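test_that("makeGenome plants exactly the requested motif copies", {
  zero <- makeGenome(50000, "TCAAGCTTGA", density = 0, seed = 41)
  expect_equal(unname(genomeMotifDensity(zero$genome, "TCAAGCTTGA")), 0)
  expect_equal(nrow(zero$planted), 0L)
  five <- makeGenome(1e6, "TCAAGCTTGA", density = 5, seed = 42)
  expect_equal(unname(five$nCopies), 5L)
  expect_equal(unname(genomeMotifDensity(five$genome, "TCAAGCTTGA")), 5)
  expect_error(makeGenome(2000, "TCAAGCTTGA", density = 5e4, seed = 1),
               "infeasible")
})

test_that("scanning a generated genome recovers exactly the planted sites", {
  g <- makeGenome(2e5, c("TCAAGCTTGA", "TTAGGG"), c(40, 30), seed = 43)
  hits <- scanMotifs(g$genome, motifSet(c("TCAAGCTTGA", "TTAGGG"),
                                        c("TCAAGCTTGA", "TTAGGG"),
                                        rep("suppressive", 2)))
  got <- hits[order(hits$motif, hits$start), c("motif", "start", "strand")]
  want <- g$planted[order(g$planted$motif, g$planted$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # non-palindromic copies alternate strands; palindromic stay forward
  expect_setequal(unique(want$strand[want$motif == "TTAGGG"]), c("+", "-"))
  expect_equal(unique(want$strand[want$motif == "TCAAGCTTGA"]), "+")
})

test_that("generated genomes are bit-identical under a fixed seed", {
  a <- makeGenome(1e5, "TTAGGG", 20, seed = 44)
  b <- makeGenome(1e5, "TTAGGG", 20, seed = 44)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$planted, b$planted)
})

test_that("community specs validate their invariants", {
  expect_error(communitySpec(c("A", "B"), 1e5, c(TCAAGCTTGA = 2),
                             c(0.6, 0.6), c(0.5, 0.5), seed = 1),
               "sum to 1")
  expect_error(communitySpec(c("A", "B"), 1e5, c(TCAAGCTTGA = -1),
                             c(0.5, 0.5), c(0.5, 0.5), seed = 1),
               ">= 0")
  ok <- defaultCommunitySpec(seed = 3)
  expect_s4_class(ok, "CommunitySpec")
  expect_equal(colSums(ok@abundance), c(C = 1, E = 1))
  # the two planted conditions: 6x focal abundance, 1.5x expected density
  expect_equal(unname(ok@abundance["Bifidobacterium", "C"] /
                      ok@abundance["Bifidobacterium", "E"]), 6)
  dens <- ok@motifDensity[, "TCAAGCTTGA"]
  expect_equal(unname(sum(ok@abundance[, "C"] * dens) /
                      sum(ok@abundance[, "E"] * dens)), 1.5)
})

test_that("error-free simulations emit perfect alignment identities", {
  spec <- communitySpec(c("A", "B"), 5e4, c(TCAAGCTTGA = 20),
                        c(0.5, 0.5), c(0.2, 0.8), nPerGroup = 1,
                        readsPerSample = 500, readLength = 100,
                        errorRate = 0, seed = 45)
  sim <- simulateSamples(spec, withQualities = FALSE)
  for (s in names(sim$hits))
    expect_true(all(sim$hits[[s]]$identity == 100))
  # reads reconstruct exactly from truth coordinates
  tr <- sim$truth$reads[["C1"]]
  for (j in c(1, 100, 400)) {
    g <- sim$genomes[[paste0(tr$taxon[j], "_genome")]]
    w <- Biostrings::subseq(g, tr$start[j], tr$start[j] + 99)
    if (tr$strand[j] == "-") w <- Biostrings::reverseComplement(w)
    expect_identical(as.character(w),
                     as.character(sim$reads[["C1"]][[j]]))
  }
})

test_that("alignment identities equal 100 (1 - realized error fraction)", {
  spec <- communitySpec("A", 5e4, c(TTAGGG = 10), 1, 1, nPerGroup = 1,
                        readsPerSample = 300, readLength = 100,
                        errorRate = 0.02, seed = 46)
  sim <- simulateSamples(spec, withQualities = FALSE)
  tr <- sim$truth$reads[["C1"]]
  h <- sim$hits[["C1"]]
  expect_equal(h$identity, 100 * (1 - tr$errors / 100))
  # realized mismatches against the source window match the recorded count
  nm <- vapply(1:50, function(j) {
    g <- sim$genomes[[1]]
    w <- Biostrings::subseq(g, tr$start[j], tr$start[j] + 99)
    if (tr$strand[j] == "-") w <- Biostrings::reverseComplement(w)
    Biostrings::neditAt(as.character(w), sim$reads[["C1"]][[j]])
  }, numeric(1))
  expect_equal(nm, tr$errors[1:50])
})

test_that("single-taxon communities profile to 100% of their genus", {
  spec <- communitySpec("Bifidobacterium", 5e4, c(TCAAGCTTGA = 4), 1, 1,
                        nPerGroup = 1, readsPerSample = 400,
                        readLength = 100, errorRate = 0.005, seed = 47)
  sim <- simulateSamples(spec, withQualities = FALSE)
  tp <- taxonProfile(sim$hits[["C1"]],
                     hitFilter(minIdentity = 40, minQueryCov = 0.5),
                     sim$taxonMap, level = "genus")
  expect_equal(tp$profile$taxon, "Bifidobacterium")
  expect_equal(tp$profile$relAbundance, 100)
})

test_that("simulated cohorts are deterministic and write standard formats", {
  spec <- defaultCommunitySpec(seed = 48, nPerGroup = 2,
                               readsPerSample = 1500)
  sim <- simulateSamples(spec)
  sim2 <- simulateSamples(spec)
  expect_identical(as.character(sim$reads[["E2"]]),
                   as.character(sim2$reads[["E2"]]))
  expect_identical(sim$hits[["C1"]], sim2$hits[["C1"]])
  expect_identical(as.character(sim$genomes), as.character(sim2$genomes))
  expect_equal(unname(colSums(sim$truth$composition)), rep(1500, 4))
  # qualities ride along and round-trip through FASTQ on disk
  expect_s4_class(sim$reads[["C1"]], "QualityScaledDNAStringSet")
  od <- file.path(tempdir(), "simout")
  simulateSamples(spec, outDir = od)
  expect_true(file.exists(file.path(od, "C1.fastq")))
  back <- readSequences(file.path(od, "C1.fastq"))
  expect_identical(as.character(back), as.character(sim$reads[["C1"]]))
  hitsBack <- readBlastTab(file.path(od, "C1_hits.tsv"),
                           queryLengths = setNames(
                             rep(spec@readLength, 1500),
                             names(sim$reads[["C1"]])))
  expect_equal(nrow(hitsBack), 1500)
  expect_equal(hitsBack$identity, sim$hits[["C1"]]$identity)
  expect_true(file.exists(file.path(od, "truth.json")))
  expect_true(file.exists(file.path(od, "genomes.fasta")))
})

test_that("sample composition tracks group abundances", {
  spec <- defaultCommunitySpec(seed = 49, nPerGroup = 3,
                               readsPerSample = 20000)
  sim <- simulateSamples(spec, withQualities = FALSE)
  comp <- sim$truth$composition
  frac <- sweep(comp, 2, colSums(comp), "/")
  expC <- spec@abundance[, "C"]; expE <- spec@abundance[, "E"]
  # each taxon fraction within 4 binomial standard errors of its target
  for (tx in rownames(comp)) {
    seC <- sqrt(expC[tx] * (1 - expC[tx]) / 20000)
    expect_lt(max(abs(frac[tx, 1:3] - expC[tx])), 4 * seC + 1e-6)
  }
})
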