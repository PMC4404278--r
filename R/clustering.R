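#' @include AllClasses.R AllGenerics.R
NULL

#' Pearson correlation distance
#'
#' `d(i, j) = 1 - r(i, j)` between the row (or column) profiles, giving a
#' symmetric matrix with zero diagonal and range `[0, 2]`.
#'
#' @param x Numeric matrix.
#' @param margin 1 to compare rows (genes), 2 to compare columns (samples).
#' @return Symmetric distance matrix.
#' @export
pearsonDistance <- function(x, margin = 2) {
  stopifnot(is.matrix(x), margin %in% 1:2)
  if (margin == 1L) x <- t(x)
  if (ncol(x) < 2L) stop("need at least two items", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant profile(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  d <- 1 - cor(x)
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering
#'
#' Average-linkage (default) agglomerative clustering of a distance matrix,
#' as used for the sample dendrograms; a thin wrapper over
#' [stats::hclust()].  Export the result with [writeNewick()].
#'
#' @param d Distance matrix or `dist` object.
#' @param linkage Linkage method (`"average"`, `"complete"`, ...).
#' @return An `hclust` object.
#' @export
hierarchicalCluster <- function(d, linkage = "average") {
  if (anyNA(d)) stop("distance matrix contains NA/NaN", call. = FALSE)
  if (is.matrix(d)) d <- as.dist(d)
  hclust(d, method = linkage)
}

## ---------------------------------------------------------------------------
## One-way ANOVA gate (vectorized over genes)
## ---------------------------------------------------------------------------

#' One-way ANOVA gate over the colonization period
#'
#' Classical fixed-effects one-way ANOVA of each gene across the day groups,
#' Benjamini-Hochberg corrected; only genes with adjusted p below `alpha`
#' (default 0.001) pass the gate and enter consensus clustering.
#'
#' @param x Genes x samples matrix (or [FractionExperiment-class], using all
#'   its samples; subset to one compartment first).
#' @param day Vector of day labels per sample (ignored for the experiment
#'   input, which carries its own).
#' @param alpha Gate threshold on adjusted p-values.
#' @return An [AnovaGate-class].
#' @export
anovaGate <- function(x, day = NULL, alpha = 0.001) {
  if (is(x, "FractionExperiment")) {
    day <- colData(x)$day
    x <- assay(x, "exprs")
  }
  stopifnot(is.matrix(x), length(day) == ncol(x))
  g <- factor(day)
  k <- nlevels(g)
  if (k < 2L) stop("need at least two time points", call. = FALSE)
  counts <- table(g)
  if (any(counts < 2L))
    stop("each day needs at least two replicates", call. = FALSE)
  N <- ncol(x)
  ind <- vapply(levels(g), function(l) as.numeric(g == l), numeric(N))
  groupMeans <- (x %*% ind) / rep(counts, each = nrow(x))
  grand <- rowMeans(x)
  ssb <- rowSums(sweep(groupMeans, 1, grand)^2 %*% diag(as.numeric(counts)))
  sst <- rowSums((x - grand)^2)
  ssw <- sst - ssb
  df1 <- k - 1L; df2 <- N - k
  Fstat <- (ssb / df1) / (ssw / df2)
  pRaw <- pf(Fstat, df1, df2, lower.tail = FALSE)
  pRaw[ssw == 0 & ssb == 0] <- 1
  pAdj <- benjaminiHochberg(pRaw)
  tab <- data.frame(gene = rownames(x), F = Fstat, pRaw = pRaw, pAdj = pAdj,
                    row.names = NULL)
  new("AnovaGate", table = tab, alpha = alpha,
      gated = tab$gene[tab$pAdj < alpha])
}

## ---------------------------------------------------------------------------
## Consensus clustering
## ---------------------------------------------------------------------------

## Cut a tree into k clusters of size > 1, deepening the cut as needed so
## that outlier genes isolated as singletons do not consume cluster slots.
## Returns the cluster vector and which items belong to non-singleton
## clusters.
.cutNonSingleton <- function(hc, k, n) {
  h <- k
  repeat {
    cl <- cutree(hc, h)
    sizes <- table(cl)
    if (sum(sizes > 1L) >= k || h >= n) break
    h <- h + 1L
  }
  keepIds <- names(sizes)[sizes > 1L]
  keep <- cl %in% keepIds
  ## relabel the retained clusters 1..k' in order of appearance
  cl2 <- integer(length(cl))
  cl2[keep] <- as.integer(factor(cl[keep],
                                 levels = unique(cl[keep])))
  list(cl = cl2, keep = keep)
}

## area under the empirical CDF of the upper-triangular consensus values
.consensusArea <- function(m) {
  v <- sort(m[upper.tri(m)])
  if (!length(v)) return(0)
  cdf <- stats::ecdf(v)
  x <- unique(c(0, v, 1))
  sum(diff(x) * cdf(x[-length(x)]))
}

#' Subsampling-based consensus clustering of gene time profiles
#'
#' Repeatedly subsamples the gated genes without replacement, clusters each
#' subsample by average-linkage hierarchical clustering on Pearson
#' correlation distance, and accumulates how often each gene pair
#' co-clusters relative to how often it is co-sampled.  The number of
#' clusters is chosen by the consensus-CDF area criterion: K is the largest
#' scanned value whose relative increase in area under the consensus CDF is
#' at least `plateauDelta`.  Final assignments cut an average-linkage tree
#' of `1 - consensus` at the chosen K.
#'
#' @param x Genes x days matrix of replicate-averaged profiles (see
#'   [dayProfiles()]).  Profiles are z-scored across days when `standardize`
#'   is `TRUE` so that shape, not level, drives the clustering.
#' @param kRange Candidate cluster numbers (within `[2, nGenes/5]`).
#' @param nResamples Number of subsampling iterations (default 250).
#' @param subsampleFraction Fraction of genes drawn per iteration.
#' @param seed Integer seed.
#' @param standardize Z-score each gene profile across days first.
#' @param linkage Linkage for the inner and final hierarchical clustering.
#' @param innerMethod `"hclust"` (default) or `"kmeans"` for the
#'   per-resample partitioning.
#' @param plateauDelta Minimum relative area increase to accept a larger K.
#' @return A [ConsensusResult-class].
#' @export
consensusCluster <- function(x, kRange = 2:6, nResamples = 250,
                             subsampleFraction = 0.8, seed = 1L,
                             standardize = TRUE, linkage = "average",
                             innerMethod = c("hclust", "kmeans"),
                             plateauDelta = 0.1) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  innerMethod <- match.arg(innerMethod)
  n <- nrow(x)
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 2L || max(kRange) > n / 5)
    stop("kRange must lie within [2, nGenes/5]", call. = FALSE)
  if (n < 5L * max(kRange))
    stop("too few genes for the requested K range", call. = FALSE)
  if (standardize) {
    mu <- rowMeans(x); s <- apply(x, 1, sd)
    if (any(s == 0))
      stop("constant profile(s): ",
           paste(rownames(x)[s == 0], collapse = ", "), call. = FALSE)
    x <- (x - mu) / s
  }
  m <- max(2L, floor(subsampleFraction * n))
  set.seed(seed)
  coCluster <- lapply(kRange, function(k) matrix(0, n, n))
  names(coCluster) <- as.character(kRange)
  coSample <- matrix(0, n, n)
  for (b in seq_len(nResamples)) {
    idx <- sort(sample.int(n, m))
    coSample[idx, idx] <- coSample[idx, idx] + 1
    sub <- x[idx, , drop = FALSE]
    hc <- if (innerMethod == "hclust")
      hclust(as.dist(1 - cor(t(sub))), method = linkage) else NULL
    for (k in kRange) {
      if (is.null(hc)) {
        cl <- stats::kmeans(sub, centers = k, nstart = 3)$cluster
      } else {
        ## singleton (outlier) clusters do not count towards k and are
        ## excluded from the co-clustering tallies
        cut <- .cutNonSingleton(hc, k, length(idx))
        cl <- cut$cl
        cl[!cut$keep] <- 0L
      }
      ind <- vapply(seq_len(max(cl, 1L)), function(j) as.numeric(cl == j),
                    numeric(length(cl)))
      key <- as.character(k)
      coCluster[[key]][idx, idx] <- coCluster[[key]][idx, idx] +
        tcrossprod(ind)
    }
  }
  consensus <- lapply(coCluster, function(cc) {
    cm <- ifelse(coSample > 0, cc / pmax(coSample, 1), 0)
    diag(cm) <- 1
    cm <- (cm + t(cm)) / 2
    dimnames(cm) <- list(rownames(x), rownames(x))
    cm
  })
  areas <- vapply(consensus, .consensusArea, numeric(1))
  deltas <- numeric(length(kRange))
  deltas[1] <- areas[1]
  if (length(kRange) > 1L)
    deltas[-1] <- diff(areas) / areas[-length(areas)]
  names(deltas) <- names(areas)
  accepted <- which(deltas >= plateauDelta)
  chosen <- if (length(accepted)) kRange[max(accepted)] else kRange[1]
  cm <- consensus[[as.character(chosen)]]
  finalTree <- hclust(as.dist(1 - cm), method = linkage)
  cut <- .cutNonSingleton(finalTree, chosen, n)
  assignment <- cut$cl
  if (any(!cut$keep)) {
    ## outliers join the cluster they most often co-cluster with
    for (i in which(!cut$keep)) {
      aff <- vapply(seq_len(max(assignment)), function(j)
        mean(cm[i, cut$keep & assignment == j]), numeric(1))
      assignment[i] <- which.max(aff)
    }
  }
  names(assignment) <- rownames(x)
  new("ConsensusResult", consensus = consensus, kRange = kRange,
      areas = areas, deltas = deltas, chosenK = as.integer(chosen),
      assignment = assignment, profiles = data.frame())
}

#' Per-cluster mean and standard-deviation time profiles
#'
#' For each cluster and day, computes the mean and standard deviation over
#' the member genes' replicate-averaged values, plus member counts.
#'
#' @param assignment Named integer vector gene -> cluster id (e.g. from
#'   [clusterAssignment()]).
#' @param x Genes x samples matrix of the time course.
#' @param day Day label per sample.
#' @return data.frame with columns cluster, day, mean, sd, n.
#' @export
clusterProfiles <- function(assignment, x, day) {
  stopifnot(!is.null(names(assignment)))
  missing <- setdiff(names(assignment), rownames(x))
  if (length(missing))
    stop("assigned genes absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  prof <- dayProfiles(x[names(assignment), , drop = FALSE], day)
  out <- do.call(rbind, lapply(sort(unique(assignment)), function(cl) {
    members <- names(assignment)[assignment == cl]
    if (!length(members)) stop("empty cluster ", cl, call. = FALSE)
    sub <- prof[members, , drop = FALSE]
    data.frame(cluster = cl, day = as.numeric(colnames(prof)),
               mean = colMeans(sub),
               sd = apply(sub, 2, sd),
               n = length(members))
  }))
  out$sd[is.na(out$sd)] <- 0  # single-gene cluster
  rownames(out) <- NULL
  out
}
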