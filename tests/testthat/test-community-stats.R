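test_that("Shannon diversity matches its closed forms", {
  expect_equal(shannonDiversity(c(10, 0, 0)), 0)
  for (k in c(2, 5, 8))
    expect_equal(shannonDiversity(rep(7, k)), log(k))
  expect_error(shannonDiversity(c(0, 0)), "all-zero")
  set.seed(55)
  for (i in 1:20) {
    x <- rpois(30, 5)
    x[1] <- x[1] + 1  # guarantee nonzero
    p <- x[x > 0] / sum(x)
    expect_equal(shannonDiversity(x), -sum(p * log(p)))
    expect_equal(shannonDiversity(x, base = 2), -sum(p * log2(p)))
  }
})

test_that("Chao1 matches the closed form and never drops below S_obs", {
  expect_equal(chao1Richness(c(5, 5, 3)), 3)          # no singletons
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4))             # S=10, F1=4, F2=2
  expect_equal(chao1Richness(x), 14)
  # F2 = 0 falls back to the bias-corrected form
  y <- c(rep(1, 3), rep(5, 4))                        # S=7, F1=3, F2=0
  expect_equal(chao1Richness(y), 7 + 3 * 2 / 2)
  expect_equal(chao1Richness(x, biasCorrected = TRUE), 10 + 4 * 3 / 6)
  set.seed(66)
  for (i in 1:50) {
    v <- rpois(40, 2)
    if (sum(v) == 0) v[1] <- 1
    expect_gte(chao1Richness(v), sum(v > 0))
    expect_gte(chao1Richness(v, biasCorrected = TRUE), sum(v > 0))
  }
})

test_that("rarefaction subsampling is exact at the margins and seeded", {
  x <- c(a = 5, b = 3, c = 2)
  expect_equal(rarefyCounts(x, 10), as.integer(x),
               ignore_attr = "names")
  one <- rarefyCounts(x, 1, seed = 1)
  expect_equal(sum(one), 1L)
  expect_equal(sum(one > 0), 1L)
  expect_error(rarefyCounts(x, 11), "depth")
  expect_identical(rarefyCounts(x, 5, seed = 9), rarefyCounts(x, 5, seed = 9))
})

test_that("mean rarefied richness matches the hypergeometric expectation", {
  set.seed(77)
  counts <- rpois(25, 8)
  counts[counts == 0] <- 1
  depth <- floor(sum(counts) / 2)
  analytic <- expectedRichness(counts, depth)
  mc <- rarefactionCurve(counts, depth, nReps = 1000, seed = 5)
  expect_lt(abs(mc$meanSObs - analytic), 4 * mc$sdSObs / sqrt(1000) + 0.05)
  # and against the independent vegan implementation
  expect_equal(analytic, as.numeric(vegan::rarefy(counts, depth)),
               tolerance = 1e-8)
})

test_that("rarefaction curves are nondecreasing in depth", {
  set.seed(88)
  counts <- rpois(30, 6) + 1
  depths <- c(5, 20, 50, 100, sum(counts))
  cv <- rarefactionCurve(counts, depths, nReps = 200, seed = 3)
  expect_true(all(diff(cv$meanSObs) >= 0))
  expect_true(all(diff(expectedRichness(counts, depths)) >= 0))
})

test_that("per-sample diversity estimates honour the rarefaction depth", {
  set.seed(99)
  otu <- matrix(rpois(3 * 40, 30), nrow = 3,
                dimnames = list(paste0("s", 1:3), paste0("otu", 1:40)))
  d <- diversityEstimates(otu, depth = 100, nReps = 20, seed = 4)
  expect_equal(d$sample, paste0("s", 1:3))
  expect_true(all(d$chao1 >= d$sObs - 1e-9))
  expect_true(all(d$shannon >= 0 & d$shannon <= log(40)))
  expect_identical(d, diversityEstimates(otu, depth = 100, nReps = 20,
                                         seed = 4))
})

test_that("OTU tables round-trip through TSV", {
  otu <- matrix(1:6, nrow = 2,
                dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tf <- tempfile(fileext = ".tsv")
  write.table(otu, tf, sep = "\t", quote = FALSE, col.names = NA)
  expect_equal(readOtuTable(tf), otu)
})

test_that("Mann-Whitney handles ties, symmetry and complete separation", {
  same <- mannWhitneyTest(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(same$p, 1)
  sep <- mannWhitneyTest(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$p, 0.1)
  expect_equal(sep$U, 9)
  # U is invariant to monotone transforms
  expect_equal(mannWhitneyTest(exp(c(5, 6, 7)), exp(c(1, 2, 3)))$U, sep$U)
})

test_that("exact Mann-Whitney p equals full-enumeration oracle", {
  set.seed(111)
  for (i in 1:40) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    tied <- i %% 2 == 0
    x <- if (tied) sample(1:4, n1, replace = TRUE) else rnorm(n1)
    y <- if (tied) sample(1:4, n2, replace = TRUE) else rnorm(n2)
    got <- mannWhitneyTest(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, mwOracle(x, y))
  }
})

test_that("large-sample Mann-Whitney agrees with wilcox.test", {
  set.seed(122)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  got <- mannWhitneyTest(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(got$method, "normal")
  expect_equal(unname(got$U), unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
})

test_that("fold-change reports ratios of group mean proportions", {
  mat <- rbind(f1 = c(13, 13, 8, 8), f2 = c(987, 987, 992, 992))
  g <- c("C", "C", "E", "E")
  fc <- foldChangeReport(mat, g)
  expect_equal(fc$foldChange[1], 1.3 / 0.8, tolerance = 1e-12)
  expect_equal(fc$foldChange[2], 98.7 / 99.2, tolerance = 1e-12)
  eq <- foldChangeReport(rbind(a = c(5, 5, 5, 5)), g, toProportions = FALSE)
  expect_equal(eq$foldChange, 1)
  # zero denominators are NA unless rescued with a pseudo-proportion
  z <- rbind(a = c(2, 3, 0, 0), b = c(98, 97, 100, 100))
  expect_true(is.na(foldChangeReport(z, g)$foldChange[1]))
  expect_false(is.na(foldChangeReport(z, g, pseudo = TRUE)$foldChange[1]))
})

test_that("planted fold changes are recovered from simulated counts", {
  fm <- simulateFeatureMatrix(30, 6, 5e4, planted = c(feature5 = 5),
                              seed = 13)
  counts <- SummarizedExperiment::assay(fm$se)
  fc <- foldChangeReport(counts, SummarizedExperiment::colData(fm$se)$group)
  # truth: planted proportion ratio after renormalization
  trueFold <- fm$truth$propC["feature5"] / fm$truth$propE["feature5"]
  expect_equal(fc$foldChange[5], unname(trueFold), tolerance = 0.1)
})

test_that("OLS fit returns exact slope, correlation and sane bands", {
  x <- 1:10
  fit <- olsFit(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$pearsonR, 1)
  set.seed(133)
  xr <- rnorm(40); yr <- 0.7 * xr + rnorm(40)
  f2 <- olsFit(xr, yr, confidence = 0.95)
  expect_equal(f2$pearsonR, cov(xr, yr) / (sd(xr) * sd(yr)))
  expect_equal(f2$slope, cov(xr, yr) / var(xr))
  expect_true(all(f2$bands$lwr <= f2$bands$fit & f2$bands$fit <= f2$bands$upr))
  expect_error(olsFit(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Jarque-Bera accepts normal samples and rejects skewed ones", {
  set.seed(144)
  ok <- vapply(1:20, function(i) jarqueBera(rnorm(1000))$p > 0.05, TRUE)
  expect_gte(mean(ok), 0.9)
  skewed <- jarqueBera(rexp(1000))
  expect_lt(skewed$p, 0.001)
  # closed form on a fixed vector
  v <- c(1, 2, 3, 4, 10)
  m <- v - mean(v)
  S <- mean(m^3) / mean(m^2)^1.5
  K <- mean(m^4) / mean(m^2)^2
  expect_equal(jarqueBera(v)$statistic, 5 / 6 * (S^2 + (K - 3)^2 / 4))
})
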