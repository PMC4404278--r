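#' @include AllClasses.R AllGenerics.R
NULL

#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' across-sample mean of the order statistics.  After normalization each
#' column's sorted value vector is identical.  Tied values within a column
#' receive the mean of the tied order-statistic targets (average ranks).
#'
#' @param x Numeric matrix (genes x samples) with at least two columns, or a
#'   [FractionExperiment-class] whose `exprs` assay is normalized in place.
#' @return Object of the same class as `x`.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantileNormalize(m)  # both columns become 2.5, 3.5, 4.5
#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
  if (ncol(x) < 2L)
    stop("quantile normalization needs at least two samples", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (target[lo] + target[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
setMethod("quantileNormalize", "FractionExperiment", function(x) {
  assay(x, "exprs") <- quantileNormalize(assay(x, "exprs"))
  x
})

#' Log2-transform a matrix when it looks linear-scale
#'
#' Microarray matrices are sometimes deposited on the linear scale.  When the
#' matrix maximum exceeds `threshold` (default 50, far above any plausible
#' log2 intensity) the matrix is log2-transformed; the decision is recorded
#' in the `"log2Applied"` attribute (or metadata entry for a
#' [FractionExperiment-class]).
#'
#' @param x Numeric matrix or [FractionExperiment-class].
#' @param threshold Transform when `max(x) > threshold`.
#' @param force `"auto"` (default heuristic), `"log2"` (always transform) or
#'   `"none"` (never).
#' @return Object of the same class as `x`.
#' @rdname log2IfNeeded
#' @export
setMethod("log2IfNeeded", "matrix", function(x, threshold = 50,
                                             force = c("auto", "log2",
                                                       "none")) {
  force <- match.arg(force)
  apply2 <- switch(force, auto = max(x) > threshold, log2 = TRUE,
                   none = FALSE)
  if (apply2) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "cannot log2-transform: %d non-positive value(s), first at [%s, %s]",
        nrow(bad), rownames(x)[bad[1, 1]] %||% bad[1, 1],
        colnames(x)[bad[1, 2]] %||% bad[1, 2]), call. = FALSE)
    x <- log2(x)
  }
  attr(x, "log2Applied") <- apply2
  x
})

#' @rdname log2IfNeeded
setMethod("log2IfNeeded", "FractionExperiment",
          function(x, threshold = 50, force = c("auto", "log2", "none")) {
  m <- log2IfNeeded(assay(x, "exprs"), threshold, force)
  applied <- attr(m, "log2Applied")
  attr(m, "log2Applied") <- NULL
  assay(x, "exprs") <- m
  metadata(x)$log2Applied <- applied
  x
})

`%||%` <- function(a, b) if (is.null(a)) b else a
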