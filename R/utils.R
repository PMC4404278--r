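#' Derive a child seed from a pipeline-level seed
#'
#' All stochastic operations in the package take an explicit seed.  A single
#' pipeline-level seed is fanned out to the individual stages through this
#' counter-based scheme so that each stage is independently reproducible and
#' stages do not share RNG streams.
#'
#' @param seed Integer master seed.
#' @param stream Integer stream counter (>= 0) identifying the consumer.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' childSeed(1, 0)
#' childSeed(1, 1)
#' @export
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; products stay < 2^53
  s <- (abs(as.double(seed)) %% m)
  s <- (s * 48271 + as.double(stream) * 16807 + 1) %% m
  as.integer(s)
}

## shared argument checks -----------------------------------------------------

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

.fractionKey <- function(tissue, fraction) paste(tissue, fraction, sep = "_")

## replicate-averaged day profiles: genes x unique days -----------------------

#' Average replicates per time point
#'
#' Collapses a genes-by-samples matrix to a genes-by-days matrix of replicate
#' means, with days ordered numerically.
#'
#' @param x Numeric matrix, genes in rows.
#' @param day Vector of day labels, one per column of `x`.
#' @return Matrix with one column per unique day (numeric order).
#' @export
dayProfiles <- function(x, day) {
  stopifnot(is.matrix(x), length(day) == ncol(x))
  lev <- as.character(sort(unique(as.numeric(as.character(day)))))
  day <- as.character(as.numeric(as.character(day)))
  out <- vapply(lev, function(d) rowMeans(x[, day == d, drop = FALSE]),
                numeric(nrow(x)))
  dimnames(out) <- list(rownames(x), lev)
  out
}
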