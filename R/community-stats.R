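#' Shannon diversity of a count vector
#'
#' `-sum(p_i * log(p_i))` over nonzero proportions, in nats by default (the
#' logarithm base is configurable since reported indices do not always state
#' it).
#'
#' @param counts non-negative counts (one community).
#' @param base logarithm base (default `exp(1)`: nats).
#' @return Shannon index.
#' @examples
#' shannonDiversity(rep(10, 8))  # log(8)
#' @export
shannonDiversity <- function(counts, base = exp(1)) {
  if (sum(counts) <= 0) stop("all-zero community: diversity undefined")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Chao1 richness of a count vector
#'
#' Classic form `S_obs + F1^2 / (2 F2)` with singleton count F1 and doubleton
#' count F2; when F2 = 0 (or with `biasCorrected = TRUE` always) the
#' bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used. Always
#' at least `S_obs`.
#'
#' @param counts non-negative integer counts.
#' @param biasCorrected use the bias-corrected form throughout (default
#'   FALSE: classic, falling back to bias-corrected only when F2 = 0).
#' @return Estimated richness.
#' @examples
#' chao1Richness(c(rep(1, 4), rep(2, 2), rep(5, 10)))  # 16 + 16/4 = 20
#' @export
chao1Richness <- function(counts, biasCorrected = FALSE) {
  if (sum(counts) <= 0) stop("all-zero community: richness undefined")
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (biasCorrected || f2 == 0)
    sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else
    sObs + f1^2 / (2 * f2)
}

#' Rarefy a count vector
#'
#' Subsamples `depth` individuals without replacement (deterministic given
#' `seed`).
#'
#' @param counts non-negative integer counts.
#' @param depth subsample size; must not exceed `sum(counts)`.
#' @param seed optional integer seed.
#' @return Integer vector of rarefied counts (same length/names as `counts`).
#' @export
rarefyCounts <- function(counts, depth, seed = NULL) {
  if (depth > sum(counts)) stop("depth exceeds total count")
  withSeed(seed, {
    # rrarefy warns whenever the smallest nonzero count exceeds 1, which is
    # routine for rarefied count data; the warning is spurious here
    as.integer(suppressWarnings(vegan::rrarefy(counts, depth)))
  }) |> stats::setNames(names(counts))
}

#' Expected richness under rarefaction (analytic)
#'
#' Hypergeometric closed form for the expected number of taxa observed in a
#' without-replacement subsample of size `depth`:
#' `sum_i (1 - choose(N - N_i, depth) / choose(N, depth))`.
#'
#' @param counts non-negative integer counts.
#' @param depth subsample size(s).
#' @return Expected observed richness, one value per depth.
#' @export
expectedRichness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  vapply(depth, function(n) {
    if (n > N) stop("depth exceeds total count")
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1))
}

#' Monte-Carlo rarefaction curve
#'
#' Mean observed richness over `nReps` random subsamples at each depth.
#'
#' @param counts non-negative integer counts.
#' @param depths increasing subsample sizes.
#' @param nReps subsamples per depth (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with `depth`, `meanSObs`, `sdSObs`.
#' @export
rarefactionCurve <- function(counts, depths, nReps = 1000, seed = NULL) {
  withSeed(seed, {
    res <- vapply(depths, function(d) {
      s <- vapply(seq_len(nReps), function(i)
        sum(suppressWarnings(vegan::rrarefy(counts, d)) > 0), numeric(1))
      c(mean(s), stats::sd(s))
    }, numeric(2))
    data.frame(depth = depths, meanSObs = res[1, ], sdSObs = res[2, ])
  })
}

#' Per-sample diversity estimates at a fixed rarefaction depth
#'
#' For each sample, subsamples to `depth` (`nReps` times) and reports the
#' mean observed richness, Shannon index and Chao1 richness over the
#' subsamples — the standard way alpha diversity is compared across unevenly
#' sequenced samples (e.g. 7,000 sequences per sample).
#'
#' @param otu samples x taxa count matrix (rows named by sample).
#' @param depth rarefaction depth (default 7000).
#' @param nReps subsamples per sample (default 100).
#' @param seed optional integer seed.
#' @param biasCorrected passed to [chao1Richness()].
#' @return data.frame with one row per sample: `sample`, `depth`, `sObs`,
#'   `shannon`, `chao1`, `nReps`.
#' @export
diversityEstimates <- function(otu, depth = 7000, nReps = 100, seed = NULL,
                               biasCorrected = FALSE) {
  otu <- as.matrix(otu)
  withSeed(seed, {
    rows <- lapply(rownames(otu), function(s) {
      x <- otu[s, ]
      reps <- vapply(seq_len(nReps), function(i) {
        r <- as.integer(suppressWarnings(vegan::rrarefy(x, depth)))
        c(sum(r > 0), shannonDiversity(r), chao1Richness(r, biasCorrected))
      }, numeric(3))
      data.frame(sample = s, depth = depth, sObs = mean(reps[1, ]),
                 shannon = mean(reps[2, ]), chao1 = mean(reps[3, ]),
                 nReps = nReps, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Read an OTU table (samples x taxa TSV)
#'
#' Tab-separated with a header of taxon names and sample ids in the first
#' column.
#'
#' @param path path to the TSV.
#' @return Integer matrix, samples in rows.
#' @export
readOtuTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

# 2*U for group x against y, with midrank ties: counts pairs (i, j) with
# x_i > y_j as 2 and ties as 1, so everything stays integer.
twoU <- function(x, y) {
  r <- rank(c(x, y))
  2 * sum(r[seq_along(x)]) - length(x) * (length(x) + 1)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank tie handling. For small samples
#' (both groups at most `exactMax`) the p-value is exact, from full
#' enumeration of all `choose(n1+n2, n1)` group-label arrangements:
#' `p = P(|U - mu| >= |U_obs - mu|)` under the permutation distribution.
#' Larger samples use the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param x,y numeric samples for the two groups.
#' @param exactMax largest per-group size for the exact path (default 10).
#' @return list with `U` (for `x`), `p`, and `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' mannWhitneyTest(c(5, 6, 7), c(1, 2, 3))$p  # 0.1: complete separation
#' @export
mannWhitneyTest <- function(x, y, exactMax = 10) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups need at least one observation")
  u2 <- twoU(x, y)                      # 2*U, integer under midranks
  mu2 <- n1 * n2                        # 2*mu
  if (max(n1, n2) <= exactMax) {
    pooled <- c(x, y)
    r <- rank(pooled)
    combs <- utils::combn(n1 + n2, n1)
    u2perm <- 2 * colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1)
    p <- mean(abs(u2perm - mu2) >= abs(u2 - mu2))
    return(list(U = u2 / 2, p = p, method = "exact"))
  }
  N <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = u2 / 2, p = 1, method = "normal"))
  z <- (abs(u2 - mu2) / 2 - 0.5) / sqrt(sigma2)
  list(U = u2 / 2, p = min(1, 2 * stats::pnorm(-max(z, 0))),
       method = "normal")
}

#' Per-feature fold change between groups
#'
#' Ratio of group-C to group-E mean relative abundances per feature, with a
#' delta-method standard deviation. Features whose group-E mean is zero are
#' reported as `NA` unless `pseudo = TRUE`, which adds the additive
#' pseudo-proportion `1 / (2 * max(colSums(mat)))` before forming ratios.
#'
#' @param mat features x samples matrix of counts (converted to within-sample
#'   proportions when `toProportions = TRUE`, the default) or of relative
#'   abundances.
#' @param group factor/character per sample with levels C and E (C first).
#' @param toProportions divide each column by its sum first (default TRUE).
#' @param pseudo add the pseudo-proportion to rescue zero denominators
#'   (default FALSE).
#' @return data.frame `feature`, `meanC`, `meanE`, `foldChange`, `foldSd`,
#'   `log2Fold`.
#' @export
foldChangeReport <- function(mat, group, toProportions = TRUE,
                             pseudo = FALSE) {
  mat <- as.matrix(mat)
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly two groups required")
  P <- if (toProportions) sweep(mat, 2, colSums(mat), "/") else mat
  if (pseudo) P <- P + 1 / (2 * max(colSums(mat)))
  gC <- group == lev[1]; gE <- group == lev[2]
  meanC <- rowMeans(P[, gC, drop = FALSE])
  meanE <- rowMeans(P[, gE, drop = FALSE])
  sdC <- apply(P[, gC, drop = FALSE], 1, stats::sd)
  sdE <- apply(P[, gE, drop = FALSE], 1, stats::sd)
  fc <- ifelse(meanE > 0, meanC / meanE, NA_real_)
  foldSd <- fc * sqrt(ifelse(meanC > 0, (sdC / meanC)^2 / sum(gC), NA) +
                      (sdE / meanE)^2 / sum(gE))
  data.frame(feature = rownames(P) %||% as.character(seq_len(nrow(P))),
             meanC = meanC, meanE = meanE, foldChange = fc,
             foldSd = foldSd, log2Fold = log2(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least squares fit with Pearson correlation and confidence bands
#'
#' Closed-form simple linear regression, the Pearson correlation of x and y
#' with its two-sided test, and pointwise confidence bands for the fitted
#' mean at the requested level.
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @param confidence band level (default 0.95).
#' @param nBand number of points at which to evaluate the bands.
#' @return list with `slope`, `intercept`, `pearsonR`, `pearsonP`,
#'   `confidence`, `bands` (data.frame `x`, `fit`, `lwr`, `upr`), `model`
#'   (the `lm` fit).
#' @export
olsFit <- function(x, y, confidence = 0.95, nBand = 50) {
  if (length(x) < 3 || length(x) != length(y))
    stop("need n >= 3 paired observations")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  ct <- stats::cor.test(x, y)
  grid <- data.frame(x = seq(min(x), max(x), length.out = nBand))
  pb <- stats::predict(fit, grid, interval = "confidence",
                       level = confidence)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearsonR = unname(ct$estimate), pearsonP = ct$p.value,
       confidence = confidence,
       bands = data.frame(x = grid$x, fit = pb[, "fit"],
                          lwr = pb[, "lwr"], upr = pb[, "upr"]),
       model = fit)
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` from sample skewness S and kurtosis K
#' (central-moment estimators), compared to a chi-squared distribution with
#' 2 degrees of freedom.
#'
#' @param values numeric sample, `n >= 4`.
#' @return list with `statistic`, `p`, `skewness`, `kurtosis`.
#' @export
jarqueBera <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  m <- values - mean(values)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  if (m2 == 0) stop("zero variance")
  S <- m3 / m2^1.5
  K <- m4 / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p = stats::pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K)
}
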