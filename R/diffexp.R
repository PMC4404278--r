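#' @include AllClasses.R AllGenerics.R
#' @importFrom stats rnorm rgamma rbinom pt pnorm pf phyper dhyper rhyper
#'   p.adjust sd var cor setNames qf cov lm anova aov as.dist cutree hclust
#'   coef
NULL

## ---------------------------------------------------------------------------
## Empirical-Bayes variance prior (scaled-F model)
## ---------------------------------------------------------------------------

## Newton inversion of the trigamma function, y > 0.
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the hyperparameters (d0, s0sq) of the scaled-F model underlying
#' the moderated t-test by moment-matching the log residual variances: the
#' mean and variance of log(s2) are matched to the model's
#' digamma/trigamma expressions.  When the observed variance of log(s2) does
#' not exceed trigamma(dg/2) the trigamma equation has no positive solution;
#' d0 is then infinite (no excess dispersion of the gene variances) and s0sq
#' is the mean of the variances.
#'
#' @param s2 Numeric vector of per-gene residual variances (log2 units
#'   squared).
#' @param dg Residual degrees of freedom common to all genes (>= 1).
#' @return A [ModeratedTPrior-class].
#' @export
fitVariancePrior <- function(s2, dg) {
  .assertScalarNum(dg, "dg", lower = 1)
  s2 <- s2[is.finite(s2)]
  if (all(s2 <= 0)) stop("all residual variances are zero", call. = FALSE)
  if (length(s2) < 50)
    warning("fewer than 50 genes; variance prior estimate is unstable")
  pos <- s2 > 0
  if (!all(pos)) {
    warning(sprintf("%d zero variance(s) excluded from prior fit",
                    sum(!pos)))
    s2 <- s2[pos]
  }
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- var(e)
  excess <- evar - trigamma(dg / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * .trigammaInverse(excess)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- mean(s2)
  }
  new("ModeratedTPrior", d0 = d0, s0sq = s0sq)
}

## ---------------------------------------------------------------------------
## Moderated t contrast
## ---------------------------------------------------------------------------

.moderatedT <- function(x, colsA, colsB, prior = NULL, label = "contrast") {
  nA <- length(colsA); nB <- length(colsB)
  if (nA < 2L || nB < 2L)
    stop("each group needs at least two samples", call. = FALSE)
  if (length(intersect(colsA, colsB)))
    stop("groups must be disjoint", call. = FALSE)
  a <- x[, colsA, drop = FALSE]; b <- x[, colsB, drop = FALSE]
  mA <- rowMeans(a); mB <- rowMeans(b)
  dg <- nA + nB - 2
  ssA <- rowSums((a - mA)^2); ssB <- rowSums((b - mB)^2)
  s2 <- (ssA + ssB) / dg
  if (is.null(prior)) prior <- fitVariancePrior(s2, dg)
  d0 <- prior@d0; s0sq <- prior@s0sq
  s2post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + dg * s2) / (d0 + dg)
  md <- mA - mB
  se <- sqrt(s2post * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, md / se, ifelse(md == 0, 0, sign(md) * Inf))
  df <- d0 + dg
  pRaw <- if (is.infinite(df)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df)
  pRaw[se == 0 & md == 0] <- 1
  tab <- data.frame(gene = rownames(x), meanDiff = md, s2 = s2,
                    s2Post = s2post, t = t, df = df, pRaw = pRaw,
                    pAdj = benjaminiHochberg(pRaw), row.names = NULL)
  new("ContrastResult", table = tab, prior = prior, label = label,
      nA = as.integer(nA), nB = as.integer(nB))
}

#' Moderated t-test contrast between two sample groups
#'
#' Per gene, the pooled residual variance is shrunk towards the prior:
#' `s2Post = (d0*s0sq + dg*s2) / (d0 + dg)`; the moderated t-statistic is
#' `meanDiff / sqrt(s2Post * (1/nA + 1/nB))` with `d0 + dg` degrees of
#' freedom (a normal reference when `d0 = Inf`).  P-values are two-sided and
#' Benjamini-Hochberg adjusted.  With no prior supplied the prior is fitted
#' from this contrast's own variances ([fitVariancePrior()]), one prior per
#' compartment since fractions are analyzed separately throughout.
#'
#' For the matrix method, `groupA`/`groupB` are column names or indices
#' (A minus B).  For a [FractionExperiment-class], give `tissue` and
#' `fraction`; the contrast is CR minus GF within that compartment.
#'
#' @param x Matrix of log2 intensities or a [FractionExperiment-class].
#' @param ... Method arguments, see Details.
#' @return A [ContrastResult-class].
#' @rdname moderatedTContrast
#' @export
setMethod("moderatedTContrast", "matrix",
          function(x, groupA, groupB, prior = NULL, label = "contrast") {
  .moderatedT(x, groupA, groupB, prior, label)
})

#' @rdname moderatedTContrast
#' @param tissue,fraction Compartment selector for the experiment method.
#' @param groupA,groupB Sample selectors (matrix method) or status labels
#'   (experiment method; defaults CR vs GF).
#' @param prior Optional pre-fitted [ModeratedTPrior-class].
#' @param label Contrast label (defaults to the fraction key).
setMethod("moderatedTContrast", "FractionExperiment",
          function(x, tissue, fraction, groupA = "CR", groupB = "GF",
                   prior = NULL, label = .fractionKey(tissue, fraction)) {
  cd <- colData(x)
  if (!"status" %in% names(cd))
    stop("experiment has no 'status' annotation", call. = FALSE)
  sel <- cd$tissue == tissue & cd$fraction == fraction
  colsA <- colnames(x)[sel & cd$status == groupA]
  colsB <- colnames(x)[sel & cd$status == groupB]
  .moderatedT(assay(x, "exprs"), colsA, colsB, prior, label)
})

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment:
#' `pAdj_(i) = min_{j >= i} min(1, m * p_(j) / j)`, mapped back to input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
benjaminiHochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

## ---------------------------------------------------------------------------
## Venn partitioning and fraction specificity
## ---------------------------------------------------------------------------

.vennFromSets <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  universe <- unique(unlist(sets, use.names = FALSE))
  nm <- names(sets)
  memb <- matrix(vapply(sets, function(s) universe %in% s,
                        logical(length(universe))),
                 nrow = length(universe), dimnames = list(NULL, nm))
  keys <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "+")))
  regions <- setNames(integer(length(keys)), keys)
  if (length(universe)) {
    sig <- apply(memb, 1, function(r) paste(nm[r], collapse = "+"))
    tabulated <- table(sig)
    regions[names(tabulated)] <- as.integer(tabulated)
  }
  new("VennPartition", sets = lapply(sets, as.character), regions = regions,
      universe = universe)
}

#' Venn partition of significant genes across fractions
#'
#' Thresholds each contrast at `alpha` on adjusted p-values (default 0.001,
#' the headline cutoff) and partitions the union of significant genes over
#' all 2^n - 1 intersection regions of the per-fraction sets.
#'
#' @param contrasts Named list of [ContrastResult-class] objects (one per
#'   fraction, sharing the same gene universe), or a named list of character
#'   vectors interpreted directly as significant sets.
#' @param alpha Significance threshold on adjusted p-values.
#' @return A [VennPartition-class].
#' @export
significantSets <- function(contrasts, alpha = 0.001) {
  if (all(vapply(contrasts, is.character, logical(1))))
    return(.vennFromSets(contrasts))
  stopifnot(all(vapply(contrasts, is, logical(1), "ContrastResult")))
  universes <- lapply(contrasts, function(cr) sort(cr@table$gene))
  if (!all(vapply(universes, identical, logical(1), universes[[1]])))
    stop("contrasts do not share a gene universe", call. = FALSE)
  sets <- lapply(contrasts, function(cr)
    cr@table$gene[cr@table$pAdj < alpha])
  .vennFromSets(sets)
}

#' Fraction-specificity summary
#'
#' Counts genes falling in exclusive (single-fraction) Venn regions and
#' reports the percentage of the union they represent, rounded to the
#' nearest integer.  The numeric method takes the exclusive region counts
#' directly together with the union size, which allows summarizing published
#' Venn counts.
#'
#' @param x A [VennPartition-class], or a numeric vector of exclusive region
#'   counts.
#' @param ... For the numeric method: `total`, the union size.
#' @return List with `nSpecific`, `nTotal` and `percentSpecific` (integer;
#'   `NA` for an empty union).
#' @examples
#' specificitySummary(c(340, 894, 273, 444), total = 2256)  # 86 percent
#' @rdname specificitySummary
#' @export
setMethod("specificitySummary", "VennPartition", function(x, ...) {
  excl <- sum(x@regions[names(x@sets)])
  specificitySummary(as.numeric(excl), total = length(x@universe))
})

#' @rdname specificitySummary
#' @param total Union size (numeric method).
setMethod("specificitySummary", "numeric", function(x, total) {
  nSpec <- sum(x)
  if (total == 0)
    return(list(nSpecific = 0L, nTotal = 0L, percentSpecific = NA_integer_))
  list(nSpecific = as.integer(nSpec), nTotal = as.integer(total),
       percentSpecific = as.integer(round(100 * nSpec / total)))
})
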