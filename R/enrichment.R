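#' @include AllClasses.R AllGenerics.R
NULL

#' Fisher (hypergeometric) over-representation test
#'
#' One-sided over-representation p-value for the overlap between a gene list
#' and a term set within a universe: the hypergeometric upper tail
#' `P(X >= k)` with `K` term genes among `N`, drawing `n`.
#'
#' @param geneList Character vector (subset of `universe`, non-empty).
#' @param termSet Character vector of term genes; members outside the
#'   universe are ignored for the counts.
#' @param universe Character vector of all genes.
#' @return List with `k`, `n`, `K`, `N` and `fisherP`.
#' @export
fisherEnrichment <- function(geneList, termSet, universe) {
  if (!length(geneList)) stop("gene list is empty", call. = FALSE)
  bad <- setdiff(geneList, universe)
  if (length(bad))
    stop("gene list outside universe: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  termSet <- intersect(termSet, universe)
  N <- length(universe); K <- length(termSet)
  n <- length(unique(geneList)); k <- length(intersect(geneList, termSet))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, fisherP = p)
}

#' Empirical random-sampling background p-value
#'
#' The null reference used for regulator enrichment: the mean Fisher p-value
#' of `nDraws` (default 1,000) uniformly drawn gene lists of the same size.
#' Since the Fisher p-value depends on a random list only through its
#' overlap with the term, the overlap is drawn directly from its
#' hypergeometric distribution.
#'
#' @param listSize Size of the observed gene list.
#' @param termSet Character vector of term genes.
#' @param universe Character vector of all genes.
#' @param nDraws Number of random draws (>= 1).
#' @param seed Integer seed.
#' @return Mean background p-value (scalar).
#' @export
empiricalBackground <- function(listSize, termSet, universe, nDraws = 1000,
                                seed = 1L) {
  .assertScalarNum(nDraws, "nDraws", lower = 1)
  if (listSize > length(universe))
    stop("list size exceeds the universe", call. = FALSE)
  termSet <- intersect(termSet, universe)
  N <- length(universe); K <- length(termSet)
  set.seed(seed)
  k <- rhyper(nDraws, K, N - K, listSize)
  mean(phyper(k - 1, K, N - K, listSize, lower.tail = FALSE))
}

#' Regulator / microRNA target enrichment with empirical background
#'
#' For each regulator target set, computes the Fisher over-representation
#' p-value of the gene list and the empirical background p-value from random
#' lists of the same size.  A regulator is called enriched when its observed
#' p-value beats the background (`fisherP < backgroundP`) and falls below
#' `pCeiling`.  Records are ranked by ascending Fisher p.
#'
#' @param geneList Character vector of (e.g. microbiota-regulated) genes.
#' @param targets [GeneSetCollection-class] or named list: regulator ->
#'   target genes.
#' @param universe Character vector of all genes.
#' @param nDraws Background draws per regulator (default 1,000).
#' @param pCeiling Significance ceiling for the enrichment call.
#' @param seed Integer seed.
#' @return An [EnrichmentResult-class] (mode `"regulators"`) with columns
#'   id, k, n, K, N, fisherP, backgroundP, enrichmentRatio
#'   (`backgroundP / fisherP`) and enriched.
#' @export
regulatorEnrichment <- function(geneList, targets, universe, nDraws = 1000,
                                pCeiling = 0.05, seed = 1L) {
  if (is(targets, "GeneSetCollection")) targets <- geneSets(targets)
  keep <- lengths(lapply(targets, intersect, universe)) > 0L
  if (any(!keep))
    warning(sprintf("%d regulator(s) with empty target sets skipped",
                    sum(!keep)))
  targets <- targets[keep]
  rows <- lapply(seq_along(targets), function(i) {
    fe <- fisherEnrichment(geneList, targets[[i]], universe)
    bg <- empiricalBackground(fe$n, targets[[i]], universe, nDraws,
                              seed = childSeed(seed, i))
    data.frame(id = names(targets)[i], k = fe$k, n = fe$n, K = fe$K,
               N = fe$N, fisherP = fe$fisherP, backgroundP = bg,
               enrichmentRatio = bg / max(fe$fisherP, .Machine$double.xmin))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$fisherP, -tab$k, tab$id), ]
  rownames(tab) <- NULL
  tab$enriched <- tab$fisherP < tab$backgroundP & tab$fisherP < pCeiling
  new("EnrichmentResult", table = tab, mode = "regulators",
      params = list(nDraws = nDraws, pCeiling = pCeiling, seed = seed))
}

#' Gene-set (GO-style) enrichment with member and significance filters
#'
#' Hypergeometric over-representation per term, Benjamini-Hochberg adjusted
#' across terms.  A term passes when its adjusted p-value is below
#' `pCeiling` (default 1e-5) and its overlap with the gene list has more
#' than `minMembers` genes (default 5); term sizes count only genes present
#' in the universe.  `log10pAdj` is exported for heatmap display.
#'
#' @param geneList Character vector of genes to test.
#' @param collection [GeneSetCollection-class] of terms.
#' @param universe Character vector of all genes.
#' @param minMembers A passing term needs strictly more overlap members.
#' @param pCeiling Threshold on adjusted p-values.
#' @return An [EnrichmentResult-class] (mode `"genesets"`) with columns id,
#'   k, n, K, N, fisherP, pAdj, log10pAdj, passesFilter.
#' @export
geneSetEnrichment <- function(geneList, collection, universe,
                              minMembers = 5, pCeiling = 1e-5) {
  if (minMembers < 1) stop("minMembers must be >= 1", call. = FALSE)
  sets <- if (is(collection, "GeneSetCollection")) geneSets(collection) else
    collection
  if (!length(sets))
    return(new("EnrichmentResult",
               table = data.frame(id = character(), k = integer(),
                                  n = integer(), K = integer(),
                                  N = integer(), fisherP = numeric(),
                                  pAdj = numeric(), log10pAdj = numeric(),
                                  passesFilter = logical()),
               mode = "genesets",
               params = list(minMembers = minMembers, pCeiling = pCeiling)))
  rows <- lapply(names(sets), function(id) {
    fe <- fisherEnrichment(geneList, sets[[id]], universe)
    data.frame(id = id, k = fe$k, n = fe$n, K = fe$K, N = fe$N,
               fisherP = fe$fisherP)
  })
  tab <- do.call(rbind, rows)
  tab$pAdj <- benjaminiHochberg(tab$fisherP)
  tab$log10pAdj <- log10(pmax(tab$pAdj, .Machine$double.xmin))
  tab$passesFilter <- tab$pAdj < pCeiling & tab$k > minMembers
  tab <- tab[order(tab$pAdj, tab$fisherP, tab$id), ]
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab, mode = "genesets",
      params = list(minMembers = minMembers, pCeiling = pCeiling))
}

#' Top-k regulators per fraction and their merged unique list
#'
#' Selects the `k` most significant regulators of each fraction (smallest
#' Fisher p; ties broken by larger overlap, then lexical id) and merges them
#' into a unique list with per-fraction membership flags.
#'
#' @param results Named list of [EnrichmentResult-class] objects (regulator
#'   mode), one per fraction.
#' @param k Number of regulators to keep per fraction (default 50).
#' @return List with `perFraction` (named list of data.frames) and `merged`
#'   (data.frame: id plus one logical membership column per fraction).
#' @export
topKRegulators <- function(results, k = 50) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  stopifnot(length(names(results)) == length(results))
  perFraction <- lapply(results, function(res) {
    tab <- if (is(res, "EnrichmentResult")) enrichmentTable(res) else res
    tab <- tab[order(tab$fisherP, -tab$k, tab$id), ]
    if (nrow(tab) < k)
      warning(sprintf("only %d records available for top-%d selection",
                      nrow(tab), k))
    utils::head(tab, k)
  })
  ids <- sort(unique(unlist(lapply(perFraction, `[[`, "id"))))
  memb <- matrix(vapply(perFraction, function(tab) ids %in% tab$id,
                        logical(length(ids))),
                 nrow = length(ids),
                 dimnames = list(NULL, names(perFraction)))
  merged <- data.frame(id = ids, memb, check.names = FALSE)
  list(perFraction = perFraction, merged = merged)
}

#' Cross-fraction specificity of enriched regulators
#'
#' From the merged top-k table, counts regulators present in all fractions
#' (shared), in exactly one (specific) and in between, with percentages
#' rounded to the nearest integer.
#'
#' @param merged data.frame as returned in `topKRegulators()$merged`.
#' @return List with `n`, `nShared`, `nSpecific`, `nIntermediate`,
#'   `percentShared`, `percentSpecific`.
#' @export
regulatorSpecificity <- function(merged) {
  flagCols <- vapply(merged, is.logical, logical(1))
  if (!any(flagCols)) stop("no membership flag columns", call. = FALSE)
  flags <- as.matrix(merged[, flagCols, drop = FALSE])
  n <- nrow(flags)
  if (n == 0L)
    return(list(n = 0L, nShared = NA_integer_, nSpecific = NA_integer_,
                nIntermediate = NA_integer_, percentShared = NA_integer_,
                percentSpecific = NA_integer_))
  counts <- rowSums(flags)
  nShared <- sum(counts == ncol(flags))
  nSpecific <- sum(counts == 1L)
  list(n = n, nShared = as.integer(nShared),
       nSpecific = as.integer(nSpecific),
       nIntermediate = as.integer(n - nShared - nSpecific),
       percentShared = as.integer(round(100 * nShared / n)),
       percentSpecific = as.integer(round(100 * nSpecific / n)))
}
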