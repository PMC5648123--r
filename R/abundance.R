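#' Recruit reads to target sequences
#'
#' Applies the recruitment screen (default > 95% identity and > 50% query
#' length coverage) and keeps, for every read-target pair, the single best
#' passing hit (highest bitscore, then identity, then leftmost subject
#' coordinate). A read passing for several targets contributes to each of
#' them; set `uniqueBest = TRUE` to keep only each read's single best target.
#'
#' @param hits a canonical hit table with `queryLength` available.
#' @param filter a [HitFilter-class]; default
#'   `hitFilter(minIdentity = 95, minQueryCov = 0.5)`.
#' @param uniqueBest keep only the best target per read (default FALSE).
#' @return The recruited subset of `hits`, one row per read-target pair.
#' @seealso [coverage()]
#' @export
recruitReads <- function(hits,
                         filter = hitFilter(minIdentity = 95,
                                            minQueryCov = 0.5),
                         uniqueBest = FALSE) {
  h <- hits[hitsPass(hits, filter), , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  bs <- ifelse(is.na(h$bitscore), -Inf, h$bitscore)
  qi <- match(h$query, unique(h$query))
  si <- match(h$subject, sort(unique(h$subject)))
  key <- (qi - 1) * as.double(length(unique(h$subject))) + si
  o <- order(key, -bs, -h$identity, h$subjectStart)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(key[o]), , drop = FALSE]
  if (uniqueBest) h <- bestHits(h)
  rownames(h) <- NULL
  h
}

#' Normalized sequence coverage
#'
#' For each target, the lengths of all recruited reads are summed and divided
#' by the target length (raw coverage), then normalized to a 10 Gb dataset:
#' `normCoverage = rawCoverage * 1e10 / datasetBases`. This makes per-target
#' abundance comparable across metagenomes of different sizes.
#'
#' @param targetLengths named numeric, target length in bases per target id.
#' @param recruited recruited hit table from [recruitReads()].
#' @param datasetBases total bases in the (preprocessed) metagenome.
#' @param mappedBasesFrom `"queryLength"` (default: mapped read length, the
#'   summed quantity in the definition) or `"alignLength"`.
#' @return data.frame with one row per target: `target`, `targetLength`,
#'   `nReads`, `mappedBases`, `rawCoverage`, `normCoverage`. Targets with no
#'   recruited reads get zero coverage.
#' @export
coverage <- function(targetLengths, recruited, datasetBases,
                     mappedBasesFrom = c("queryLength", "alignLength")) {
  mappedBasesFrom <- match.arg(mappedBasesFrom)
  if (datasetBases <= 0) stop("datasetBases must be > 0")
  if (any(targetLengths <= 0)) stop("zero-length target")
  targets <- names(targetLengths)
  if (is.null(targets)) stop("targetLengths must be named by target id")
  len <- recruited[[mappedBasesFrom]]
  if (nrow(recruited) && any(is.na(len)))
    stop("missing read lengths in recruited hits")
  mapped <- vapply(targets, function(tg)
    sum(len[recruited$subject == tg]), numeric(1))
  nReads <- vapply(targets, function(tg)
    sum(recruited$subject == tg), numeric(1))
  raw <- mapped / targetLengths
  data.frame(target = targets, targetLength = unname(targetLengths),
             nReads = unname(nReads), mappedBases = unname(mapped),
             rawCoverage = unname(raw),
             normCoverage = unname(raw * 1e10 / datasetBases),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Taxon relative-abundance profile from best hits
#'
#' Queries are assigned to the taxon of their best passing hit (bitscore,
#' then identity, then lexicographic subject id). Relative abundance is the
#' percentage of *annotated* queries assigned to each taxon (percentages of
#' the classified community); unclassified queries are reported separately.
#'
#' @param hits a canonical hit table.
#' @param filter a [HitFilter-class]; the annotation screen uses > 40%
#'   identity and > 50% query length coverage.
#' @param taxonMap data.frame with a `subject` column plus one column per
#'   taxonomic level (e.g. `phylum`, `genus`), or a named character vector
#'   (then `level` is ignored).
#' @param level which taxonomic level column of `taxonMap` to profile.
#' @param nQueries total number of queries submitted, to count queries with
#'   no hit at all as unclassified; default: distinct queries in `hits`.
#' @return list with `level`, `profile` (data.frame `taxon`, `nReads`,
#'   `relAbundance` in percent, decreasing), `nAnnotated`, `nUnclassified`.
#' @export
taxonProfile <- function(hits,
                         filter = hitFilter(minIdentity = 40,
                                            minQueryCov = 0.5),
                         taxonMap, level = "genus", nQueries = NULL) {
  if (is.data.frame(taxonMap)) {
    if (!level %in% names(taxonMap))
      stop("taxonMap has no '", level, "' column")
    taxonMap <- stats::setNames(as.character(taxonMap[[level]]),
                                taxonMap$subject)
  }
  if (is.null(nQueries)) nQueries <- length(unique(hits$query))
  best <- bestHits(hits[hitsPass(hits, filter), , drop = FALSE])
  taxon <- unname(taxonMap[best$subject])
  taxon <- taxon[!is.na(taxon)]
  nAnnotated <- length(taxon)
  tab <- sort(table(taxon), decreasing = TRUE)
  profile <- data.frame(taxon = names(tab), nReads = as.numeric(tab),
                        relAbundance = if (nAnnotated)
                          100 * as.numeric(tab) / nAnnotated else numeric(),
                        stringsAsFactors = FALSE)
  list(level = level, profile = profile, nAnnotated = nAnnotated,
       nUnclassified = nQueries - nAnnotated)
}

#' Collapse minor categories into "Others"
#'
#' Display helper: rows of a profile below an abundance threshold are
#' aggregated into a single `"Others"` row (totals preserved).
#'
#' @param profile data.frame with `relAbundance` (and optionally `nReads` or
#'   `weight`) columns; first column identifies the feature.
#' @param threshold minimum percent relative abundance to stay separate
#'   (default 5, the "Avg. > 5%" display rule for phyla; 1 is used for
#'   genera).
#' @return The profile with minor rows merged into `"Others"`.
#' @export
collapseMinor <- function(profile, threshold = 5) {
  minor <- profile$relAbundance < threshold
  if (!any(minor)) return(profile)
  major <- profile[!minor, , drop = FALSE]
  others <- profile[1, , drop = FALSE]
  others[[1]] <- "Others"
  for (col in intersect(c("nReads", "weight", "relAbundance"),
                        names(profile)))
    others[[col]] <- sum(profile[[col]][minor])
  out <- rbind(major, others)
  rownames(out) <- NULL
  out
}

#' Functional-category relative gene abundance
#'
#' Computes, independently at each hierarchy level, the percentage of
#' read-weight assigned to each functional category:
#' `sum(weights of genes in category) / sum(all weights) * 100`. Weights are
#' per-gene recruited-read counts — either supplied directly or derived from
#' a read-vs-gene hit table (best passing hit per read). Genes without a
#' category are pooled under `"uncategorized"`.
#'
#' @param categoryMap data.frame with a `gene` column plus one column per
#'   hierarchy level (e.g. `level1`, `level2`).
#' @param weights named numeric, read count per gene id; alternative to
#'   `hits`.
#' @param hits canonical hit table of reads against genes (used with
#'   `filter` to derive per-gene read counts when `weights` is NULL).
#' @param filter a [HitFilter-class] for `hits` (default > 40% identity,
#'   > 50% query coverage).
#' @param level which category column of `categoryMap` to profile.
#' @return data.frame `category`, `weight`, `relAbundance` (percent, sums to
#'   100), decreasing.
#' @export
functionProfile <- function(categoryMap, weights = NULL, hits = NULL,
                            filter = hitFilter(minIdentity = 40,
                                               minQueryCov = 0.5),
                            level = "level1") {
  if (is.null(weights)) {
    if (is.null(hits)) stop("supply per-gene 'weights' or a 'hits' table")
    best <- bestHits(hits[hitsPass(hits, filter), , drop = FALSE])
    tab <- table(best$subject)
    weights <- stats::setNames(as.numeric(tab), names(tab))
  }
  if (!level %in% names(categoryMap))
    stop("categoryMap has no '", level, "' column")
  cat <- stats::setNames(as.character(categoryMap[[level]]),
                         categoryMap$gene)
  gene <- names(weights)
  gc <- unname(cat[gene])
  gc[is.na(gc) | !nzchar(gc)] <- "uncategorized"
  agg <- tapply(as.numeric(weights), gc, sum)
  total <- sum(agg)
  if (total <= 0) stop("total weight is zero")
  out <- data.frame(category = names(agg), weight = as.numeric(agg),
                    relAbundance = 100 * as.numeric(agg) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$relAbundance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
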