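#' @include AllClasses.R
NULL

#' Generate a crossed study design
#'
#' Builds the fully crossed tissue x fraction x condition x replicate sample
#' layout.  With statuses `GF`/`CR` and 5 replicates over 2 tissues and 2
#' fractions this reproduces the 40-array comparison design; with days
#' 0/1/3/5/7 and 3 replicates, the 60-array colonization design.
#'
#' @param tissues,fractions Character vectors of factor labels (no
#'   duplicates).
#' @param conditions Character vector: either bacterial statuses (`GF`, `CR`)
#'   or day labels (coercible to numbers).
#' @param replicatesPerGroup Integer >= 2.
#' @param seed Integer master seed stored with the design and used as the
#'   default source of child seeds by the simulators.
#' @return A [StudyDesign-class].
#' @examples
#' generateDesign(c("ileum", "colon"), c("tip", "crypt"), c("GF", "CR"), 5)
#' @export
generateDesign <- function(tissues, fractions, conditions,
                           replicatesPerGroup, seed = 1L) {
  tissues <- as.character(tissues); fractions <- as.character(fractions)
  conditions <- as.character(conditions)
  for (v in list(tissues = tissues, fractions = fractions,
                 conditions = conditions)) {
    if (anyDuplicated(v))
      stop("invalid design: duplicate labels within a factor", call. = FALSE)
  }
  .assertScalarNum(replicatesPerGroup, "replicatesPerGroup", lower = 2)
  type <- if (all(conditions %in% c("GF", "CR"))) "status" else {
    if (anyNA(suppressWarnings(as.numeric(conditions))))
      stop("conditions must be GF/CR statuses or numeric day labels",
           call. = FALSE)
    "day"
  }
  grid <- expand.grid(replicate = seq_len(replicatesPerGroup),
                      condition = conditions, fraction = fractions,
                      tissue = tissues, stringsAsFactors = FALSE)
  grid <- grid[, c("tissue", "fraction", "condition", "replicate")]
  prefix <- if (type == "day") "d" else ""
  grid$sample <- sprintf("%s_%s_%s%s_r%d", grid$tissue, grid$fraction,
                         prefix, grid$condition, grid$replicate)
  new("StudyDesign", tissues = tissues, fractions = fractions,
      conditions = conditions, conditionType = type,
      replicates = as.integer(replicatesPerGroup),
      samples = grid[, c("sample", "tissue", "fraction", "condition",
                         "replicate")],
      seed = as.integer(seed))
}

#' Simulate a GF-versus-CR expression experiment with known ground truth
#'
#' Generates log2 intensities for a crossed GF/CR design.  Per-gene baselines
#' are normal (mean `baselineMean`, sd `baselineSd`) on the log2 scale;
#' per-gene tissue and fraction offsets create the compartment structure that
#' dominates sample clustering; a fraction of genes carries an additive
#' microbiota-status effect (CR relative to GF), either in a single randomly
#' assigned (tissue, fraction) compartment (`fractionSpecificRate`) or in all
#' compartments (`sharedRate`).  Effect sizes are gamma-distributed around
#' `effectSizeMean` with random sign.
#'
#' @param design A [StudyDesign-class] with status conditions.
#' @param nGenes Number of genes (>= 100).
#' @param fractionSpecificRate,sharedRate Proportions of genes regulated in
#'   one compartment / in all compartments; their sum must be <= 1.
#' @param effectSizeMean Mean absolute log2 effect size of regulated genes.
#' @param noiseSd Residual (replicate) standard deviation, log2 units.
#' @param tissueEffectSd,fractionEffectSd Standard deviations of the per-gene
#'   tissue and fraction baseline offsets.
#' @param effectShape Gamma shape of the effect-size distribution.
#' @param baselineMean,baselineSd Per-gene baseline distribution.
#' @param seed Integer seed (default: fanned out from the design seed).
#' @return A [FractionExperiment-class]; the planted truth is available via
#'   [groundTruth()].
#' @export
simulateExpression <- function(design, nGenes = 20000,
                               fractionSpecificRate = 0.086,
                               sharedRate = 0.014, effectSizeMean = 2,
                               noiseSd = 0.4, tissueEffectSd = 0.8,
                               fractionEffectSd = 1.5, effectShape = 12,
                               baselineMean = 7, baselineSd = 2,
                               seed = childSeed(design@seed, 1L)) {
  stopifnot(is(design, "StudyDesign"))
  if (design@conditionType != "status")
    stop("simulateExpression requires a GF/CR status design", call. = FALSE)
  .assertScalarNum(nGenes, "nGenes", lower = 100)
  .assertScalarNum(noiseSd, "noiseSd", lower = .Machine$double.eps)
  .assertScalarNum(fractionSpecificRate, "fractionSpecificRate", 0, 1)
  .assertScalarNum(sharedRate, "sharedRate", 0, 1)
  if (fractionSpecificRate + sharedRate > 1)
    stop("regulated-gene rates must sum to at most 1", call. = FALSE)
  .assertScalarNum(effectSizeMean, "effectSizeMean", lower = 0)

  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(nGenes))
  samp <- design@samples
  keys <- .fractionKey(samp$tissue, samp$fraction)
  fracKeys <- unique(keys)

  baseline <- rnorm(nGenes, baselineMean, baselineSd)
  tissueOff <- matrix(rnorm(nGenes * length(design@tissues), 0, tissueEffectSd),
                      nGenes, dimnames = list(genes, design@tissues))
  fracOff <- matrix(rnorm(nGenes * length(design@fractions), 0,
                          fractionEffectSd),
                    nGenes, dimnames = list(genes, design@fractions))

  nSpec <- round(fractionSpecificRate * nGenes)
  nShared <- round(sharedRate * nGenes)
  regGenes <- sample(genes, nSpec + nShared)
  specGenes <- regGenes[seq_len(nSpec)]
  sharedGenes <- setdiff(regGenes, specGenes)
  drawEffect <- function(n) {
    if (n == 0L) return(numeric(0))
    mag <- if (effectSizeMean > 0)
      rgamma(n, shape = effectShape, rate = effectShape / effectSizeMean)
    else rep(0, n)
    mag * sample(c(-1, 1), n, replace = TRUE)
  }
  assignedKey <- sample(fracKeys, nSpec, replace = TRUE)
  regulated <- lapply(fracKeys, function(k) {
    g <- specGenes[assignedKey == k]
    setNames(drawEffect(length(g)), g)
  })
  names(regulated) <- fracKeys
  regulated$shared <- setNames(drawEffect(nShared), sharedGenes)

  effectMat <- matrix(0, nGenes, length(fracKeys),
                      dimnames = list(genes, fracKeys))
  for (k in fracKeys) {
    e <- regulated[[k]]
    effectMat[names(e), k] <- e
  }
  effectMat[sharedGenes, ] <- regulated$shared[sharedGenes]

  vals <- matrix(rnorm(nGenes * nrow(samp), 0, noiseSd), nGenes,
                 dimnames = list(genes, samp$sample))
  vals <- vals + baseline + tissueOff[, samp$tissue] + fracOff[, samp$fraction]
  cr <- samp$condition == "CR"
  vals[, cr] <- vals[, cr] + effectMat[, keys[cr]]

  gt <- new("GroundTruth", universe = genes,
            regulated = regulated[c(fracKeys, "shared")])
  ann <- data.frame(sample = samp$sample, tissue = samp$tissue,
                    fraction = samp$fraction, status = samp$condition,
                    replicate = samp$replicate)
  FractionExperiment(vals, ann, groundTruth = gt)
}

#' Default time-course response archetypes
#'
#' Four mean log2 trajectories over the colonization days, reflecting the
#' response classes seen in colonized epithelium: (1) a strong step increase,
#' (2) a strong step decrease, (3) a mild gradual increase and (4) a mild
#' gradual decrease.  The step of the strong archetypes falls between days 3
#' and 5 for ileum-like kinetics and between days 1 and 3 for colon-like
#' kinetics (the colonic epithelium responds faster); the mild archetypes
#' ramp linearly with day so that magnitude classes remain distinguishable
#' under a correlation metric.
#'
#' @param tissue Tissue label; any label containing "colon" gets the early
#'   step, all others the late step.
#' @param days Numeric day grid.
#' @param strongStep,mildAmplitude Log2 magnitudes of the strong step and the
#'   mild ramp (defaults 2 and 0.75).
#' @return A 4 x length(days) matrix, rows = archetypes.
#' @export
defaultArchetypeShapes <- function(tissue, days = c(0, 1, 3, 5, 7),
                                   strongStep = 2, mildAmplitude = 0.75) {
  stepDay <- if (grepl("colon", tissue, ignore.case = TRUE)) 3 else 5
  up <- strongStep * as.numeric(days >= stepDay)
  ramp <- mildAmplitude * (days - min(days)) / diff(range(days))
  shapes <- rbind(up, -up, ramp, -ramp)
  dimnames(shapes) <- list(paste0("archetype", 1:4), as.character(days))
  shapes
}

#' Simulate a colonization time-course experiment
#'
#' Generates log2 intensities over a day-structured design.  Genes carrying a
#' planted status effect in a compartment (per the supplied
#' [GroundTruth-class]) follow one of four response archetypes in that
#' compartment's samples and are flat elsewhere; unregulated genes are flat
#' everywhere.  If the ground truth carries no archetype assignments yet,
#' regulated genes are assigned archetypes at the given proportions (shared
#' genes get the same archetype in every compartment) and the returned
#' object's ground truth is updated accordingly.
#'
#' @param design A [StudyDesign-class] with day conditions.
#' @param truth A [GroundTruth-class] naming the regulated genes per
#'   compartment (e.g. from [simulateExpression()]).
#' @param archetypeShapes Named list tissue -> 4 x days matrix of mean
#'   trajectories; default [defaultArchetypeShapes()] per tissue.
#' @param noiseSd Residual standard deviation, log2 units.
#' @param archetypeProportions Probabilities of archetypes 1..4 when
#'   assignments have to be drawn (mild classes are more populous).
#' @param baselineMean,baselineSd Per-gene baseline distribution.
#' @param seed Integer seed.
#' @return A [FractionExperiment-class] with updated ground truth.
#' @export
simulateTimecourse <- function(design, truth, archetypeShapes = NULL,
                               noiseSd = 0.1,
                               archetypeProportions = c(0.15, 0.15, 0.35, 0.35),
                               baselineMean = 7, baselineSd = 2,
                               seed = childSeed(design@seed, 2L)) {
  stopifnot(is(design, "StudyDesign"), is(truth, "GroundTruth"))
  if (design@conditionType != "day")
    stop("simulateTimecourse requires a day-structured design", call. = FALSE)
  .assertScalarNum(noiseSd, "noiseSd", lower = 0)
  days <- as.numeric(design@conditions)
  if (is.null(archetypeShapes)) {
    archetypeShapes <- lapply(setNames(design@tissues, design@tissues),
                              defaultArchetypeShapes, days = days)
  }
  for (tis in design@tissues) {
    sh <- archetypeShapes[[tis]]
    if (is.null(sh) || nrow(sh) < 4L || ncol(sh) != length(days))
      stop(sprintf("missing or malformed archetype shapes for tissue '%s'",
                   tis), call. = FALSE)
  }

  set.seed(seed)
  genes <- truth@universe
  samp <- design@samples
  keys <- .fractionKey(samp$tissue, samp$fraction)
  fracKeys <- unique(.fractionKey(
    rep(design@tissues, each = length(design@fractions)),
    rep(design@fractions, times = length(design@tissues))))

  assign <- truth@clusterAssignments
  if (length(assign) == 0L) {
    sharedGenes <- names(truth@regulated[["shared"]])
    sharedArch <- setNames(sample(1:4, length(sharedGenes), replace = TRUE,
                                  prob = archetypeProportions), sharedGenes)
    assign <- lapply(setNames(fracKeys, fracKeys), function(k) {
      g <- names(truth@regulated[[k]])
      own <- setNames(sample(1:4, length(g), replace = TRUE,
                             prob = archetypeProportions), g)
      c(own, sharedArch)
    })
    truth@clusterAssignments <- assign
    validObject(truth)
  }

  vals <- matrix(rnorm(length(genes) * nrow(samp), 0, noiseSd),
                 length(genes), dimnames = list(genes, samp$sample))
  vals <- vals + rnorm(length(genes), baselineMean, baselineSd)
  dayIdx <- match(as.numeric(samp$condition), days)
  for (k in fracKeys) {
    a <- assign[[k]]
    if (!length(a)) next
    tis <- samp$tissue[match(k, keys)]
    sh <- archetypeShapes[[tis]]
    cols <- which(keys == k)
    vals[names(a), cols] <- vals[names(a), cols] +
      sh[a, dayIdx[cols], drop = FALSE]
  }

  ann <- data.frame(sample = samp$sample, tissue = samp$tissue,
                    fraction = samp$fraction, day = as.numeric(samp$condition),
                    replicate = samp$replicate)
  FractionExperiment(vals, ann, groundTruth = truth)
}

#' Generate a gene-set collection with planted enrichment
#'
#' Builds GO-like terms over the gene universe.  Truly enriched terms draw
#' each member from the regulated list with probability `enrichmentStrength`
#' (and uniformly from the universe otherwise); null terms are uniform
#' samples, so their overlap with any fixed list follows the hypergeometric
#' law.
#'
#' @param universe Character vector of gene ids.
#' @param regulated Character vector of regulated gene ids (the list the
#'   enriched terms are biased towards).
#' @param nTerms Total number of terms (> 0).
#' @param nEnriched Number of truly enriched terms.
#' @param termSizeRange Integer range of term sizes.
#' @param enrichmentStrength Probability in `[0, 1]` that a member of an
#'   enriched term is drawn from the regulated list.
#' @param seed Integer seed.
#' @return A [GeneSetCollection-class]; the planted term ids are in
#'   `metadata`-style attribute `enriched` (also retrievable via
#'   `attr(x, "enriched")`).
#' @export
generateGeneSets <- function(universe, regulated, nTerms = 100,
                             nEnriched = 10, termSizeRange = c(10, 200),
                             enrichmentStrength = 0.8, seed = 1L) {
  if (nTerms <= 0) stop("nTerms must be positive", call. = FALSE)
  .assertScalarNum(enrichmentStrength, "enrichmentStrength", 0, 1)
  if (max(termSizeRange) > length(universe))
    stop("term sizes exceed the universe size", call. = FALSE)
  set.seed(seed)
  nEnriched <- min(nEnriched, nTerms)
  sizePool <- seq(termSizeRange[1], termSizeRange[2])
  sizes <- sizePool[sample.int(length(sizePool), nTerms, replace = TRUE)]
  ids <- sprintf("T%03d", seq_len(nTerms))
  enrichedIds <- if (nEnriched > 0) ids[seq_len(nEnriched)] else character()
  sets <- vector("list", nTerms)
  names(sets) <- ids
  for (i in seq_len(nTerms)) {
    s <- sizes[i]
    if (ids[i] %in% enrichedIds && length(regulated)) {
      fromReg <- rbinom(1, s, enrichmentStrength)
      fromReg <- min(fromReg, length(regulated))
      members <- sample(regulated, fromReg)
      rest <- setdiff(universe, members)
      members <- c(members, sample(rest, s - fromReg))
    } else {
      members <- sample(universe, s)
    }
    sets[[i]] <- members
  }
  desc <- setNames(ifelse(ids %in% enrichedIds, "planted enriched term",
                          "null term"), ids)
  out <- GeneSetCollection(sets, desc)
  attr(out, "enriched") <- enrichedIds
  out
}

#' Generate promoter sequences with planted motif sites
#'
#' Emits one promoter (default 1 kb) per gene as i.i.d. background sequence
#' from the given base frequencies; for genes named in the planting plan, the
#' motif's consensus sequence is written at a random position on a random
#' strand, and the position/strand are recorded in the returned plan.
#'
#' @param universe Character vector of gene ids.
#' @param motifs List of [MotifMatrix-class] objects.
#' @param plantingPlan Named list motif id -> character vector of gene ids to
#'   receive the consensus site (may be empty).
#' @param promoterLength Promoter length in bases (default 1000).
#' @param backgroundBaseFreqs Frequencies of A, C, G, T (must sum to 1).
#' @param seed Integer seed.
#' @return List with elements `promoters` (a
#'   [Biostrings::DNAStringSet]) and `planted` (data.frame gene, motif,
#'   start (0-based), strand).
#' @export
generatePromoters <- function(universe, motifs, plantingPlan = list(),
                              promoterLength = 1000,
                              backgroundBaseFreqs = rep(0.25, 4), seed = 1L) {
  if (abs(sum(backgroundBaseFreqs) - 1) > 1e-6)
    stop("background base frequencies must sum to 1", call. = FALSE)
  motifs <- if (is(motifs, "MotifMatrix")) list(motifs) else motifs
  names(motifs) <- vapply(motifs, function(m) m@id, character(1))
  widths <- vapply(motifs, function(m) ncol(m@mat), integer(1))
  if (length(widths) && promoterLength < max(widths))
    stop("motif longer than promoter", call. = FALSE)
  if (length(plantingPlan) && !all(names(plantingPlan) %in% names(motifs)))
    stop("planting plan references unknown motifs", call. = FALSE)

  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(universe, function(g)
    paste(sample(bases, promoterLength, replace = TRUE,
                 prob = backgroundBaseFreqs), collapse = ""), character(1))
  planted <- data.frame(gene = character(), motif = character(),
                        start = integer(), strand = character())
  for (m in names(plantingPlan)) {
    cons <- consensusSequence(motifs[[m]])
    w <- nchar(cons)
    for (g in plantingPlan[[m]]) {
      start <- sample.int(promoterLength - w + 1L, 1L) - 1L  # 0-based
      strand <- sample(c("+", "-"), 1L)
      site <- if (strand == "+") cons else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
      substr(seqs[g], start + 1L, start + w) <- site
      planted <- rbind(planted, data.frame(gene = g, motif = m,
                                           start = start, strand = strand))
    }
  }
  list(promoters = Biostrings::DNAStringSet(setNames(seqs, universe)),
       planted = planted)
}

#' Simulate a qPCR Ct table
#'
#' Emits per-well Ct values for a set of target genes plus the L32 reference
#' gene over a GF/CR design.  Target Ct decreases by log2(fold) in CR
#' samples, so a true fold change f yields an expected delta-delta-Ct of
#' -log2(f).
#'
#' @param design A [StudyDesign-class] with status conditions.
#' @param foldChanges Named numeric vector: target gene -> CR/GF fold change
#'   (> 0), applied in every compartment.
#' @param referenceGene Reference gene id (default `"L32"`).
#' @param ctRefMean Mean Ct of the reference gene.
#' @param targetOffset Baseline Ct offset of targets above the reference.
#' @param noiseSd Per-well Ct noise (cycles).
#' @param seed Integer seed.
#' @return data.frame with columns sample, gene, tissue, fraction, status,
#'   replicate, reference (logical), ct.
#' @export
simulateQpcr <- function(design, foldChanges, referenceGene = "L32",
                         ctRefMean = 18, targetOffset = 6, noiseSd = 0.2,
                         seed = childSeed(design@seed, 3L)) {
  stopifnot(is(design, "StudyDesign"))
  if (design@conditionType != "status")
    stop("simulateQpcr requires a GF/CR status design", call. = FALSE)
  if (any(foldChanges <= 0))
    stop("fold changes must be positive", call. = FALSE)
  .assertScalarNum(noiseSd, "noiseSd", lower = 0)
  set.seed(seed)
  samp <- design@samples
  rows <- list()
  for (g in c(referenceGene, names(foldChanges))) {
    isRef <- g == referenceGene
    level <- if (isRef) rep(1, nrow(samp)) else
      ifelse(samp$condition == "CR", foldChanges[[g]], 1)
    ct <- (if (isRef) ctRefMean else ctRefMean + targetOffset) -
      log2(level) + rnorm(nrow(samp), 0, noiseSd)
    rows[[g]] <- data.frame(sample = samp$sample, gene = g,
                            tissue = samp$tissue, fraction = samp$fraction,
                            status = samp$condition,
                            replicate = samp$replicate,
                            reference = isRef, ct = ct)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
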