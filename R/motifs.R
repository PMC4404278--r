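#' @include AllClasses.R AllGenerics.R
NULL

#' Consensus sequence of a motif
#'
#' The highest-probability base at each position.
#'
#' @param motif A [MotifMatrix-class].
#' @return Character scalar.
#' @export
consensusSequence <- function(motif) {
  stopifnot(is(motif, "MotifMatrix"))
  paste(rownames(motif@mat)[apply(motif@mat, 2, which.max)], collapse = "")
}

## per-base log2-odds lookup (5 x width: A C G T N, N scores 0)
.lodsTable <- function(motif) {
  lods <- log2(motif@mat / motif@background)
  rbind(lods, N = 0)
}

#' Maximum attainable log-odds score of a motif
#'
#' @param motif A [MotifMatrix-class].
#' @return Score in bits.
#' @export
maxScore <- function(motif) {
  sum(apply(log2(motif@mat / motif@background), 2, max))
}

#' Log-odds score of a single window
#'
#' `sum(log2(p_pos(base) / q(base)))` over the window, where `p` are the
#' (pseudocount-smoothed) motif probabilities and `q` the background; N
#' bases contribute 0.
#'
#' @param window Character scalar over A/C/G/T/N, same length as the motif.
#' @param motif A [MotifMatrix-class].
#' @return Score in bits.
#' @export
logOddsScore <- function(window, motif) {
  stopifnot(is(motif, "MotifMatrix"))
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != ncol(motif@mat))
    stop("window length does not match motif length", call. = FALSE)
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("window contains illegal characters", call. = FALSE)
  lut <- .lodsTable(motif)
  sum(lut[cbind(match(chars, rownames(lut)), seq_along(chars))])
}

## score every window of an integer-coded sequence (codes 1..5 = A C G T N)
.scanCodes <- function(codes, lut) {
  w <- ncol(lut)
  W <- length(codes) - w + 1L
  if (W < 1L) return(numeric(0))
  s <- numeric(W)
  for (j in seq_len(w))
    s <- s + lut[codes[j:(j + W - 1L)], j]
  s
}

#' Scan promoters with position weight matrices
#'
#' Scores every window of every promoter on both strands (the minus strand
#' via the reverse-complemented motif) and reports hits whose log-odds score
#' reaches `thresholdFraction` of the motif's maximum attainable score.  A
#' gene is a target of a motif iff it has at least one hit.  Coordinates are
#' 0-based half-open on the forward strand of the given sequence.
#'
#' @param promoters [Biostrings::DNAStringSet] or named character vector of
#'   A/C/G/T/N sequences.
#' @param motifs List of [MotifMatrix-class] objects (or a single one).
#' @param thresholdFraction Fraction of the maximum score in `(0, 1]`
#'   (default 0.8).
#' @return List with `targets` (a [GeneSetCollection-class]: motif ->
#'   target genes; motifs without targets are omitted) and `hits`
#'   (data.frame gene, motif, start, end, strand, score).
#' @export
scanPromoters <- function(promoters, motifs, thresholdFraction = 0.8) {
  if (is(promoters, "DNAStringSet")) promoters <- as.character(promoters)
  promoters <- toupper(promoters)
  if (is.null(names(promoters))) stop("promoters must be named",
                                      call. = FALSE)
  if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
  names(motifs) <- vapply(motifs, function(m) m@id, character(1))
  if (thresholdFraction <= 0 || thresholdFraction > 1)
    stop("thresholdFraction must be in (0, 1]", call. = FALSE)

  bases <- c("A", "C", "G", "T", "N")
  codeList <- lapply(promoters, function(s)
    match(strsplit(s, "")[[1]], bases))
  if (anyNA(unlist(codeList, use.names = FALSE)))
    stop("promoters contain characters outside A/C/G/T/N", call. = FALSE)

  hits <- list()
  for (m in names(motifs)) {
    lut <- .lodsTable(motifs[[m]])
    ## minus strand: reverse-complement the motif (complement rows, reverse
    ## columns); a window hit then maps to the reverse strand of the gene
    lutRC <- .lodsTable(motifs[[m]])[c(4:1, 5), rev(seq_len(ncol(lut))),
                                     drop = FALSE]
    rownames(lutRC) <- bases
    w <- ncol(lut)
    thr <- thresholdFraction * maxScore(motifs[[m]])
    for (g in names(promoters)) {
      codes <- codeList[[g]]
      if (length(codes) < w) {
        warning(sprintf("promoter '%s' shorter than motif '%s'; skipped",
                        g, m))
        next
      }
      for (strand in c("+", "-")) {
        sc <- .scanCodes(codes, if (strand == "+") lut else lutRC)
        pos <- which(sc >= thr)
        if (length(pos))
          hits[[length(hits) + 1L]] <- data.frame(
            gene = g, motif = m, start = pos - 1L, end = pos - 1L + w,
            strand = strand, score = sc[pos])
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene = character(), motif = character(), start = integer(),
               end = integer(), strand = character(), score = numeric())
  rownames(hits) <- NULL
  targetSets <- lapply(split(hits$gene, hits$motif), unique)
  targets <- GeneSetCollection(targetSets)
  list(targets = targets, hits = hits)
}
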