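#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   colData rowData
NULL

## ---------------------------------------------------------------------------
## StudyDesign
## ---------------------------------------------------------------------------

#' Crossed study design for fraction-resolved expression experiments
#'
#' Encodes the fully crossed tissue x fraction x condition x replicate layout
#' of the microarray experiments: either a germ-free (GF) versus conventionally
#' raised (CR) comparison or a colonization time course sampled on days
#' 0, 1, 3, 5 and 7.
#'
#' @slot tissues Character vector of tissue labels (e.g. ileum, colon).
#' @slot fractions Character vector of epithelial fraction labels (tip, crypt).
#' @slot conditions Character vector of condition labels: bacterial statuses
#'   (`GF`, `CR`) or colonization days.
#' @slot conditionType Either `"status"` or `"day"`.
#' @slot replicates Integer, biological replicates per group.
#' @slot samples data.frame with one row per sample (sample, tissue, fraction,
#'   condition, replicate).
#' @slot seed Integer master seed attached to the design.
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(tissues = "character", fractions = "character",
                 conditions = "character", conditionType = "character",
                 replicates = "integer", samples = "data.frame",
                 seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- NULL
  for (f in c("tissues", "fractions", "conditions")) {
    v <- slot(object, f)
    if (length(v) == 0L) msg <- c(msg, sprintf("'%s' is empty", f))
    if (anyDuplicated(v)) msg <- c(msg, sprintf("duplicate labels in '%s'", f))
  }
  if (object@replicates < 2L)
    msg <- c(msg, "replicates per group must be >= 2")
  if (!object@conditionType %in% c("status", "day"))
    msg <- c(msg, "conditionType must be 'status' or 'day'")
  nexp <- length(object@tissues) * length(object@fractions) *
    length(object@conditions) * object@replicates
  if (nrow(object@samples) != nexp)
    msg <- c(msg, "sample table does not cover the full crossed design")
  if (anyDuplicated(object@samples$sample))
    msg <- c(msg, "duplicate sample identifiers")
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic experiment
#'
#' Records what was planted by the synthetic-data generators so that recovery
#' by the analysis modules can be verified: which genes carry a
#' microbiota-status effect in which (tissue, fraction) compartment, the
#' time-course response archetype of each regulated gene, which gene-set terms
#' are truly enriched and which promoters carry a planted motif site.
#'
#' @slot universe Character vector of all gene identifiers.
#' @slot regulated Named list: one element per fraction key
#'   (`tissue_fraction`) plus optionally `"shared"`; each element a named
#'   numeric vector of per-gene log2 effect sizes.
#' @slot clusterAssignments Named list keyed by fraction key; each element a
#'   named integer vector mapping gene to archetype id (1..4).
#' @slot enrichedTerms Character vector of truly enriched term ids.
#' @slot motifTargets Named list: motif id -> data.frame(gene, start, strand).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(universe = "character", regulated = "list",
                 clusterAssignments = "list", enrichedTerms = "character",
                 motifTargets = "list"),
  prototype(universe = character(), regulated = list(),
            clusterAssignments = list(), enrichedTerms = character(),
            motifTargets = list()))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  reg <- unlist(lapply(object@regulated, names), use.names = FALSE)
  if (length(reg) && !all(reg %in% object@universe))
    msg <- c(msg, "regulated genes must be a subset of the gene universe")
  for (key in names(object@clusterAssignments)) {
    a <- object@clusterAssignments[[key]]
    pool <- c(names(object@regulated[[key]]),
              names(object@regulated[["shared"]]))
    if (!all(names(a) %in% pool))
      msg <- c(msg, sprintf(
        "archetype-assigned genes in '%s' must be regulated genes", key))
  }
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## FractionExperiment
## ---------------------------------------------------------------------------

#' Expression container for fraction-resolved experiments
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] carrying a single
#' `exprs` assay of log2 intensities together with the mandatory sample
#' annotation columns `tissue`, `fraction`, `replicate` and one of `status`
#' (GF/CR) or `day` (colonization time course).  Ground truth of synthetic
#' data sets, when available, is stored in `metadata(x)$groundTruth`.
#'
#' @exportClass FractionExperiment
setClass("FractionExperiment", contains = "SummarizedExperiment")

setValidity("FractionExperiment", function(object) {
  msg <- NULL
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- colData(object)
  need <- c("tissue", "fraction", "replicate")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData must contain tissue, fraction, replicate")
  if (sum(c("status", "day") %in% names(cd)) != 1L)
    msg <- c(msg, "colData must contain exactly one of status, day")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  if ("exprs" %in% names(assays(object)) &&
      !all(is.finite(assay(object, "exprs"))))
    msg <- c(msg, "expression values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FractionExperiment
#'
#' @param exprs Numeric matrix of log2 intensities, genes x samples, with
#'   unique row and column names.
#' @param sampleData data.frame of per-sample annotation (rows matched to
#'   columns of `exprs` by the `sample` column or row names).
#' @param groundTruth Optional [GroundTruth-class] stored in the metadata.
#' @return A [FractionExperiment-class].
#' @export
FractionExperiment <- function(exprs, sampleData, groundTruth = NULL) {
  sampleData <- as.data.frame(sampleData)
  if ("sample" %in% names(sampleData)) rownames(sampleData) <- sampleData$sample
  if (!identical(colnames(exprs), rownames(sampleData)))
    sampleData <- sampleData[colnames(exprs), , drop = FALSE]
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             colData = DataFrame(sampleData))
  obj <- new("FractionExperiment", se)
  if (!is.null(groundTruth)) metadata(obj)$groundTruth <- groundTruth
  validObject(obj)
  obj
}

## ---------------------------------------------------------------------------
## ModeratedTPrior / ContrastResult
## ---------------------------------------------------------------------------

#' Empirical-Bayes variance prior for the moderated t-test
#'
#' The scaled-F model shrinks per-gene residual variances toward a prior
#' variance `s0sq` with `d0` prior degrees of freedom; `d0 = Inf` corresponds
#' to complete shrinkage (all genes share one variance).
#'
#' @slot d0 Prior degrees of freedom (> 0, possibly `Inf`).
#' @slot s0sq Prior variance, squared log2 units (> 0).
#' @exportClass ModeratedTPrior
setClass("ModeratedTPrior", representation(d0 = "numeric", s0sq = "numeric"))

setValidity("ModeratedTPrior", function(object) {
  msg <- NULL
  if (length(object@d0) != 1L || is.na(object@d0) || object@d0 <= 0)
    msg <- c(msg, "d0 must be a positive scalar (possibly Inf)")
  if (length(object@s0sq) != 1L || !is.finite(object@s0sq) ||
      object@s0sq <= 0)
    msg <- c(msg, "s0sq must be a positive finite scalar")
  if (is.null(msg)) TRUE else msg
})

#' Result of one moderated t-test contrast
#'
#' Per-gene statistics for one CR-minus-GF comparison within a single
#' (tissue, fraction) compartment.
#'
#' @slot table data.frame with columns gene, meanDiff (log2 CR - GF), s2
#'   (pooled residual variance), s2Post (posterior variance), t (moderated t),
#'   df (total degrees of freedom), pRaw, pAdj (Benjamini-Hochberg).
#' @slot prior The fitted [ModeratedTPrior-class].
#' @slot label Contrast label (typically the fraction key).
#' @slot nA,nB Group sizes (A = CR, B = GF).
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(table = "data.frame", prior = "ModeratedTPrior",
                 label = "character", nA = "integer", nB = "integer"))

setValidity("ContrastResult", function(object) {
  tb <- object@table
  msg <- NULL
  need <- c("gene", "meanDiff", "s2", "s2Post", "t", "df", "pRaw", "pAdj")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "contrast table is missing required columns")
  else {
    if (any(tb$pRaw < 0 | tb$pRaw > 1) || any(tb$pAdj < 0 | tb$pAdj > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
    if (any(tb$pAdj + 1e-12 < tb$pRaw))
      msg <- c(msg, "adjusted p-values cannot be smaller than raw p-values")
  }
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## VennPartition
## ---------------------------------------------------------------------------

#' Partition of significant genes across fractions
#'
#' Holds the per-fraction significant gene sets and the counts of every
#' non-empty intersection region of their Venn diagram, from which
#' fraction-specific (exclusive) versus shared genes are summarized.
#'
#' @slot sets Named list of character vectors, one per fraction.
#' @slot regions Named integer vector over all 2^n - 1 membership signatures;
#'   names are `+`-joined fraction labels.
#' @slot universe Character vector: the union of all sets.
#' @exportClass VennPartition
setClass("VennPartition",
  representation(sets = "list", regions = "integer", universe = "character"))

setValidity("VennPartition", function(object) {
  msg <- NULL
  if (sum(object@regions) != length(object@universe))
    msg <- c(msg, "region counts must sum to the union size")
  if (any(object@regions < 0)) msg <- c(msg, "negative region count")
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## AnovaGate / ConsensusResult
## ---------------------------------------------------------------------------

#' One-way ANOVA gate over a colonization time course
#'
#' @slot table data.frame with columns gene, F, pRaw, pAdj.
#' @slot alpha Gate threshold on adjusted p-values.
#' @slot gated Character vector of genes passing the gate.
#' @exportClass AnovaGate
setClass("AnovaGate",
  representation(table = "data.frame", alpha = "numeric", gated = "character"))

setValidity("AnovaGate", function(object) {
  ok <- object@table$gene[object@table$pAdj < object@alpha]
  if (!setequal(ok, object@gated))
    "gated set must equal {genes: pAdj < alpha}" else TRUE
})

#' Consensus clustering result
#'
#' @slot consensus Named list of consensus matrices (values in `[0, 1]`),
#'   one per scanned K.
#' @slot kRange Integer vector of scanned cluster numbers.
#' @slot areas Area under the consensus CDF per K.
#' @slot deltas Relative increase in consensus-CDF area per K.
#' @slot chosenK Selected number of clusters.
#' @slot assignment Named integer vector gene -> cluster id (1..chosenK).
#' @slot profiles data.frame of per-cluster, per-day mean/sd/member count
#'   (empty until filled by [clusterProfiles]).
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(consensus = "list", kRange = "integer", areas = "numeric",
                 deltas = "numeric", chosenK = "integer",
                 assignment = "integer", profiles = "data.frame"))

setValidity("ConsensusResult", function(object) {
  msg <- NULL
  for (m in object@consensus) {
    if (any(m < -1e-9 | m > 1 + 1e-9)) msg <- c(msg, "consensus outside [0,1]")
    if (max(abs(m - t(m))) > 1e-9) msg <- c(msg, "consensus not symmetric")
    if (any(abs(diag(m) - 1) > 1e-9)) msg <- c(msg, "consensus diagonal != 1")
  }
  k <- object@chosenK
  if (length(k) == 1L && length(object@assignment) &&
      !all(object@assignment %in% seq_len(k)))
    msg <- c(msg, "cluster ids must lie in 1..chosenK")
  if (is.null(msg)) TRUE else unique(msg)
})

## ---------------------------------------------------------------------------
## GeneSetCollection / EnrichmentResult
## ---------------------------------------------------------------------------

#' Collection of gene sets (GO-like terms or regulator target maps)
#'
#' @slot sets Named list of character vectors (unique term ids, non-empty
#'   sets).
#' @slot descriptions Named character vector of term descriptions.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  if (anyDuplicated(names(object@sets))) msg <- c(msg, "duplicate term ids")
  if (any(lengths(object@sets) == 0L)) msg <- c(msg, "empty gene set")
  if (!identical(names(object@sets), names(object@descriptions)))
    msg <- c(msg, "descriptions must parallel the sets")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  new("GeneSetCollection", sets = sets,
      descriptions = descriptions[names(sets)])
}

#' Enrichment analysis result
#'
#' One row per term/regulator with Fisher (hypergeometric) p-value and, for
#' regulator mode, the empirical random-sampling background p-value.
#'
#' @slot table data.frame with columns id, k (overlap), n (list size), K
#'   (term size in universe), N (universe size), fisherP and mode-dependent
#'   columns (pAdj, log10pAdj, backgroundP, enrichmentRatio, passesFilter,
#'   enriched).
#' @slot mode `"genesets"` or `"regulators"`.
#' @slot params List of the parameters used.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(table = "data.frame", mode = "character", params = "list"))

## ---------------------------------------------------------------------------
## MotifMatrix
## ---------------------------------------------------------------------------

#' Position weight matrix for promoter scanning
#'
#' Column-stochastic base-probability matrix over A/C/G/T.  A pseudocount is
#' added to every cell on construction and columns renormalized, so log-odds
#' scores stay finite.
#'
#' @slot id Motif identifier.
#' @slot mat 4 x width probability matrix, rows A, C, G, T.
#' @slot background Background base frequencies (length 4, sums to 1).
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(id = "character", mat = "matrix", background = "numeric"))

setValidity("MotifMatrix", function(object) {
  msg <- NULL
  if (nrow(object@mat) != 4L || !identical(rownames(object@mat),
                                           c("A", "C", "G", "T")))
    msg <- c(msg, "probability matrix must have rows A, C, G, T")
  if (ncol(object@mat) < 4L) msg <- c(msg, "motif length must be >= 4")
  if (any(abs(colSums(object@mat) - 1) > 1e-6))
    msg <- c(msg, "motif columns must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MotifMatrix
#'
#' @param id Motif identifier.
#' @param probs Probability matrix, either 4 x width with rows A,C,G,T or
#'   width x 4 with columns A,C,G,T.
#' @param background Background base frequencies (default uniform).
#' @param pseudocount Added to each cell before column renormalization
#'   (default 0.01).
#' @return A [MotifMatrix-class].
#' @export
MotifMatrix <- function(id, probs, background = rep(0.25, 4),
                        pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) == 4L && nrow(probs) != 4L) probs <- t(probs)
  dimnames(probs) <- list(c("A", "C", "G", "T"), NULL)
  probs <- probs + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  new("MotifMatrix", id = as.character(id), mat = probs,
      background = background / sum(background))
}
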