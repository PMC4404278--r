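#' @include AllClasses.R
NULL

#' Delta-delta-Ct relative quantification
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; `ddCt` subtracts the mean
#' `dCt` of the calibrator group, and relative expression is `2^(-ddCt)`
#' (amplification efficiency fixed at 2).  By default the calibrator is the
#' GF group within each sample's own tissue/fraction compartment, so fold
#' changes are CR relative to GF per compartment.  Wells with missing Ct
#' ("not detectable") are excluded with a message.
#'
#' @param ctTable data.frame with columns sample, gene, tissue, fraction,
#'   status, ct (see [simulateQpcr()] for the layout).
#' @param targetGene Gene to quantify.
#' @param referenceGene Normalizer gene (default `"L32"`).
#' @param calibratorStatus Status label defining the calibrator group
#'   (default `"GF"`).
#' @param perCompartment Calibrate within each tissue/fraction (default) or
#'   across all samples.
#' @return data.frame with columns sample, tissue, fraction, status, dCt,
#'   ddCt, fold.
#' @export
deltaDeltaCt <- function(ctTable, targetGene, referenceGene = "L32",
                         calibratorStatus = "GF", perCompartment = TRUE) {
  need <- c("sample", "gene", "tissue", "fraction", "status", "ct")
  stopifnot(all(need %in% names(ctTable)))
  tgt <- ctTable[ctTable$gene == targetGene, ]
  ref <- ctTable[ctTable$gene == referenceGene, ]
  if (!nrow(tgt)) stop("no wells for target gene ", targetGene,
                       call. = FALSE)
  nd <- is.na(tgt$ct)
  if (any(nd)) {
    message(sprintf("%d not-detectable well(s) excluded for %s", sum(nd),
                    targetGene))
    tgt <- tgt[!nd, ]
  }
  refCt <- setNames(ref$ct, ref$sample)
  missingRef <- setdiff(tgt$sample, names(refCt)[!is.na(refCt)])
  if (length(missingRef))
    stop("missing reference measurement for sample(s): ",
         paste(missingRef, collapse = ", "), call. = FALSE)
  out <- data.frame(sample = tgt$sample, tissue = tgt$tissue,
                    fraction = tgt$fraction, status = tgt$status,
                    dCt = tgt$ct - refCt[tgt$sample])
  grp <- if (perCompartment) .fractionKey(out$tissue, out$fraction) else
    rep("all", nrow(out))
  for (g in unique(grp)) {
    sel <- grp == g
    cal <- sel & out$status == calibratorStatus
    if (!any(cal))
      stop("empty calibrator group in compartment ", g, call. = FALSE)
    out$ddCt[sel] <- out$dCt[sel] - mean(out$dCt[cal])
  }
  out$fold <- 2^(-out$ddCt)
  rownames(out) <- NULL
  out
}

#' Two-way fixed-effects ANOVA of qPCR responses
#'
#' Classical two-way ANOVA with interaction of a response (by default the
#' log-scale `dCt`) on bacterial status and epithelial fraction, using
#' Type-II sums of squares to tolerate mild imbalance (delegating to
#' [car::Anova()]).
#'
#' @param data data.frame containing the response and both factor columns.
#' @param response Response column name (default `"dCt"`).
#' @param factorA,factorB Factor column names (default status, fraction).
#' @return data.frame with one row per effect (A, B, interaction):
#'   effect, df, F, p.
#' @export
twoWayAnova <- function(data, response = "dCt", factorA = "status",
                        factorB = "fraction") {
  stopifnot(all(c(response, factorA, factorB) %in% names(data)))
  a <- factor(data[[factorA]]); b <- factor(data[[factorB]])
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least two levels", call. = FALSE)
  cellCounts <- table(a, b)
  if (any(cellCounts == 0L)) stop("empty factor cell", call. = FALSE)
  if (any(cellCounts < 2L))
    stop("each factor cell needs at least two replicates", call. = FALSE)
  df <- data.frame(y = data[[response]], A = a, B = b)
  fit <- lm(y ~ A * B, data = df)
  aov2 <- car::Anova(fit, type = 2)
  out <- data.frame(effect = c(factorA, factorB,
                               paste(factorA, factorB, sep = ":")),
                    df = aov2$Df[1:3], F = aov2$`F value`[1:3],
                    p = aov2$`Pr(>F)`[1:3])
  rownames(out) <- NULL
  out
}
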