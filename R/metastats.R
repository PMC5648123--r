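#' Build a feature-by-sample count container with group labels
#'
#' Wraps a features x samples count matrix and a two-level group factor into
#' a [SummarizedExperiment::SummarizedExperiment] (assay `"counts"`, column
#' data `group`) — the container consumed by [metastatsTest()] and
#' [foldChangeReport()].
#'
#' @param counts non-negative features x samples matrix (taxa, functional
#'   categories, motif counts, genome coverages, ...).
#' @param group character/factor per sample; the first level is the
#'   "C" (reference/control) group in fold changes.
#' @return A `SummarizedExperiment`.
#' @export
featureMatrix <- function(counts, group) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(group) != ncol(counts))
    stop("one group label per sample required")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  group <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = colnames(counts)))
}

# Welch t statistic on proportions, vectorized over features (rows of P) and
# group assignments (columns of W, a 0/1 sample-membership matrix for group
# C). Zero numerator gives t = 0 even when the variance is zero.
welchTMatrix <- function(P, W, nC, nE) {
  sumAll <- rowSums(P)
  sqAll <- rowSums(P^2)
  SC <- P %*% W
  QC <- P^2 %*% W
  meanC <- SC / nC
  meanE <- (sumAll - SC) / nE
  varC <- (QC - nC * meanC^2) / (nC - 1)
  varE <- ((sqAll - QC) - nE * meanE^2) / (nE - 1)
  varC[varC < 0] <- 0  # guard tiny negative round-off
  varE[varE < 0] <- 0
  num <- meanC - meanE
  den <- sqrt(varC / nC + varE / nE)
  t <- num / den
  t[num == 0] <- 0
  t
}

#' Metastats-style differential-abundance test
#'
#' Nonparametric two-group test for features x samples count data. Counts are
#' first converted to within-sample proportions. Dense features get an
#' unequal-variance (Welch) t statistic on the proportions with a
#' permutation p-value over group-label shuffles, using the positively biased
#' but always-valid estimator `p = (b + 1) / (B + 1)` where `b` counts
#' permutations with `|t| >= |t_obs|`. Sparse features — pooled count below
#' the sparse threshold in both groups — instead get a two-sided Fisher's
#' exact test on the pooled 2x2 table `[feature count, all-other count] x
#' [group C, group E]`. Fold change is the ratio of group mean proportions
#' (C over E).
#'
#' Samples are internally ordered by (group, sample name) before permuting,
#' so results do not depend on the column order of the input. Results are
#' exactly reproducible given `seed`.
#'
#' @param x a `SummarizedExperiment` from [featureMatrix()], or a features x
#'   samples count matrix (then `group` is required).
#' @param group group labels when `x` is a matrix; first level = group C.
#' @param nPerm number of permutations B (default 1000).
#' @param sparseThreshold a feature is sparse when its pooled count is below
#'   this in *both* groups; default `2 * samples-per-group` (per group).
#' @param alpha significance threshold (default 0.05, on unadjusted p).
#' @param seed optional integer seed for the permutation draws.
#' @param adjust `"none"` (default; raw p compared to `alpha`) or `"BH"` for
#'   a Benjamini-Hochberg `qvalue` column.
#' @return data.frame with one row per feature: `feature`, `meanC`, `meanE`
#'   (mean proportions), `foldChange`, `statistic` (t, NA on the Fisher
#'   path), `p`, `method` (`"metastats-t"`, `"fisher"`, `"degenerate"`),
#'   `sparse`, `significant`, and `qvalue` when `adjust = "BH"`. All-zero
#'   features are flagged `"degenerate"` with `p = NA`.
#' @references White, Nagarajan & Pop (2009) "Statistical methods for
#'   detecting differentially abundant features in clinical metagenomic
#'   samples", PLoS Comput Biol 5:e1000352.
#' @export
metastatsTest <- function(x, group = NULL, nPerm = 1000,
                          sparseThreshold = NULL, alpha = 0.05, seed = NULL,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is(x, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    group <- SummarizedExperiment::colData(x)$group
  } else {
    counts <- as.matrix(x)
    if (is.null(group)) stop("group labels required with a plain matrix")
  }
  group <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("need >= 2 samples per group")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))

  # canonical sample order: group then name, so column order never matters
  o <- order(group, colnames(counts))
  counts <- counts[, o, drop = FALSE]
  group <- group[o]
  gC <- group == levels(group)[1]
  nC <- sum(gC); nE <- sum(!gC); n <- nC + nE

  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every sample needs a positive total count")
  P <- sweep(counts, 2, totals, "/")

  pooledC <- rowSums(counts[, gC, drop = FALSE])
  pooledE <- rowSums(counts[, !gC, drop = FALSE])
  degenerate <- pooledC + pooledE == 0
  if (is.null(sparseThreshold)) {
    sparse <- !degenerate & pooledC < 2 * nC & pooledE < 2 * nE
  } else {
    sparse <- !degenerate & pooledC < sparseThreshold &
      pooledE < sparseThreshold
  }
  dense <- !sparse & !degenerate

  meanC <- rowMeans(P[, gC, drop = FALSE])
  meanE <- rowMeans(P[, !gC, drop = FALSE])
  fold <- ifelse(meanE > 0, meanC / meanE, NA_real_)

  stat <- rep(NA_real_, nrow(counts))
  pval <- rep(NA_real_, nrow(counts))
  method <- rep("degenerate", nrow(counts))

  if (any(dense)) {
    Pd <- P[dense, , drop = FALSE]
    Wobs <- matrix(as.numeric(gC), ncol = 1)
    tObs <- welchTMatrix(Pd, Wobs, nC, nE)[, 1]
    Wperm <- withSeed(seed, {
      idx <- replicate(nPerm, sample.int(n, nC))
      W <- matrix(0, n, nPerm)
      W[cbind(as.vector(idx), rep(seq_len(nPerm), each = nC))] <- 1
      W
    })
    tPerm <- welchTMatrix(Pd, Wperm, nC, nE)
    b <- rowSums(abs(tPerm) >= abs(tObs))
    stat[dense] <- tObs
    pval[dense] <- (b + 1) / (nPerm + 1)
    method[dense] <- "metastats-t"
  }
  if (any(sparse)) {
    totC <- sum(pooledC); totE <- sum(pooledE)
    for (i in which(sparse)) {
      tab <- matrix(c(pooledC[i], totC - pooledC[i],
                      pooledE[i], totE - pooledE[i]), nrow = 2)
      pval[i] <- stats::fisher.test(tab)$p.value
    }
    method[sparse] <- "fisher"
  }

  out <- data.frame(feature = rownames(counts), meanC = meanC,
                    meanE = meanE, foldChange = fold, statistic = stat,
                    p = pval, method = method, sparse = sparse,
                    significant = !is.na(pval) & pval < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust == "BH") {
    out$qvalue <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$qvalue) & out$qvalue < alpha
  }
  out
}
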