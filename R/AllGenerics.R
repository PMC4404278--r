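#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so that slot layout stays an implementation
#' detail: `designTable` returns the per-sample table of a design,
#' `groundTruth` the planted truth of a synthetic experiment, `contrastTable`
#' the per-gene statistics of a contrast, `priorDf`/`priorVar` the
#' empirical-Bayes hyperparameters, `vennSets`/`vennRegions` the per-fraction
#' sets and intersection-region counts, `gatedGenes` the ANOVA-gated genes,
#' `chosenK`/`clusterAssignment`/`consensusMatrix` the consensus-clustering
#' outcome, and `enrichmentTable`/`geneSets` the enrichment tables and gene
#' set lists.
#'
#' @param x An object of the corresponding class.
#' @param ... Additional arguments passed to methods.
#' @return The accessed component (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("contrastTable", function(x) standardGeneric("contrastTable"))
#' @rdname accessors
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))
#' @rdname accessors
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))
#' @rdname accessors
#' @export
setGeneric("vennSets", function(x) standardGeneric("vennSets"))
#' @rdname accessors
#' @export
setGeneric("vennRegions", function(x) standardGeneric("vennRegions"))
#' @rdname accessors
#' @export
setGeneric("gatedGenes", function(x) standardGeneric("gatedGenes"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x, ...) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname quantileNormalize
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname log2IfNeeded
#' @export
setGeneric("log2IfNeeded", function(x, threshold = 50,
                                    force = c("auto", "log2", "none"))
  standardGeneric("log2IfNeeded"))

#' @rdname moderatedTContrast
#' @export
setGeneric("moderatedTContrast", function(x, ...)
  standardGeneric("moderatedTContrast"))

#' @rdname specificitySummary
#' @export
setGeneric("specificitySummary", function(x, ...)
  standardGeneric("specificitySummary"))

## accessor methods -----------------------------------------------------------

#' @rdname accessors
setMethod("designTable", "StudyDesign", function(x) x@samples)

#' @rdname accessors
setMethod("groundTruth", "FractionExperiment",
          function(x) metadata(x)$groundTruth)

#' @rdname accessors
setMethod("contrastTable", "ContrastResult", function(x) x@table)

#' @rdname accessors
setMethod("priorDf", "ModeratedTPrior", function(x) x@d0)
#' @rdname accessors
setMethod("priorVar", "ModeratedTPrior", function(x) x@s0sq)
#' @rdname accessors
setMethod("priorDf", "ContrastResult", function(x) x@prior@d0)
#' @rdname accessors
setMethod("priorVar", "ContrastResult", function(x) x@prior@s0sq)

#' @rdname accessors
setMethod("vennSets", "VennPartition", function(x) x@sets)
#' @rdname accessors
setMethod("vennRegions", "VennPartition", function(x) x@regions)

#' @rdname accessors
setMethod("gatedGenes", "AnovaGate", function(x) x@gated)

#' @rdname accessors
setMethod("chosenK", "ConsensusResult", function(x) x@chosenK)
#' @rdname accessors
setMethod("clusterAssignment", "ConsensusResult", function(x) x@assignment)
#' @rdname accessors
#' @param k Which K to extract the consensus matrix for (default: chosen K).
setMethod("consensusMatrix", "ConsensusResult", function(x, k = chosenK(x)) {
  x@consensus[[as.character(k)]]
})

#' @rdname accessors
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@table)

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

## show methods ---------------------------------------------------------------

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign: %d tissues x %d fractions x %d %s levels x %d replicates = %d samples\n",
    length(object@tissues), length(object@fractions),
    length(object@conditions), object@conditionType, object@replicates,
    nrow(object@samples)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d genes; regulated per compartment: %s\n",
    length(object@universe),
    paste(sprintf("%s=%d", names(object@regulated),
                  lengths(object@regulated)), collapse = ", ")))
})

setMethod("show", "ModeratedTPrior", function(object) {
  cat(sprintf("ModeratedTPrior: d0 = %s, s0sq = %.4g\n",
              format(object@d0), object@s0sq))
})

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf(
    "ContrastResult '%s': %d genes, n = %d vs %d, prior d0 = %s\n",
    object@label, nrow(object@table), object@nA, object@nB,
    format(object@prior@d0)))
})

setMethod("show", "VennPartition", function(object) {
  excl <- vennRegions(object)[names(vennSets(object))]
  cat(sprintf(
    "VennPartition over %d fractions: union %d genes; exclusives: %s\n",
    length(object@sets), length(object@universe),
    paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))
})

setMethod("show", "AnovaGate", function(object) {
  cat(sprintf("AnovaGate: %d of %d genes at adjusted p < %g\n",
              length(object@gated), nrow(object@table), object@alpha))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: K scanned %s, chosen K = %d; %d genes assigned\n",
    paste(range(object@kRange), collapse = ".."), object@chosenK,
    length(object@assignment)))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %s\n",
              length(object@sets),
              paste(range(lengths(object@sets)), collapse = "..")))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult (%s): %d records\n", object@mode,
              nrow(object@table)))
})

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix '%s': width %d, consensus %s\n", object@id,
              ncol(object@mat), consensusSequence(object)))
})
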