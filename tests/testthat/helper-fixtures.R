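## Shared fixture builders; everything is generated in code at test time.

gfcrDesign <- function(reps = 5, seed = 7) {
  generateDesign(c("ileum", "colon"), c("tip", "crypt"), c("GF", "CR"),
                 reps, seed = seed)
}

timecourseDesign <- function(reps = 3, seed = 7) {
  generateDesign(c("ileum", "colon"), c("tip", "crypt"),
                 c("0", "1", "3", "5", "7"), reps, seed = seed)
}

## small deterministic expression matrix with named dims
toyMatrix <- function(nr = 6, nc = 4, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc, 8, 1), nr,
         dimnames = list(sprintf("g%02d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

## a sharply informative motif over a fixed consensus
toyMotif <- function(id = "M1", consensus = "ACGTACGTACGT", p = 0.97) {
  probs <- vapply(strsplit(consensus, "")[[1]], function(b) {
    v <- setNames(rep((1 - p) / 3, 4), c("A", "C", "G", "T"))
    v[b] <- p
    v
  }, numeric(4))
  MotifMatrix(id, probs)
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ordinary pooled two-sample t-test p-values, vectorized over rows
pooledTPvalues <- function(m, colsA, colsB) {
  a <- m[, colsA, drop = FALSE]; b <- m[, colsB, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) /
    (na + nb - 2)
  t <- (rowMeans(a) - rowMeans(b)) / sqrt(s2 * (1 / na + 1 / nb))
  2 * pt(-abs(t), na + nb - 2)
}

## brute-force step-up FDR by its definition:
## padj_i = min over {j : p_(j) >= p_(i)} of min(1, m p_(j) / j)
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

## naive O(n^3) average-linkage agglomeration; returns the merge heights and
## the cophenetic distance matrix
bruteForceAverageLinkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestD) { bestD <- dd; best <- c(i, j) }
    }
    heights[step] <- bestD
    for (a in clusters[[best[1]]]) for (b in clusters[[best[2]]])
      coph[a, b] <- coph[b, a] <- bestD
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}
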