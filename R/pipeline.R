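#' @include AllClasses.R
NULL

#' Default pipeline configuration
#'
#' Thresholds default to the study's published cutoffs: differential
#' expression and ANOVA gate at adjusted p < 0.001, gene-set filter at
#' adjusted p < 1e-5 with more than 5 overlap members, top-50 regulators per
#' fraction, 1,000 background draws.
#'
#' @param ... Overrides of the default fields.
#' @return Named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    alphaDE = 0.001, alphaGate = 0.001,
    goPCeiling = 1e-5, minMembers = 5,
    topK = 50, backgroundDraws = 1000,
    regulatorPCeiling = 0.05,
    kRange = 2:6, nResamples = 250, subsampleFraction = 0.8,
    simulation = list(nGenes = 20000, replicatesGfcr = 5,
                      replicatesTimecourse = 3),
    matrixPath = NULL, metadataPath = NULL,
    outDir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror [pipelineConfig()]; exactly one of `matrixPath` (+
#' `metadataPath`) or a `simulation` block must be present.
#'
#' @param path YAML file path.
#' @return Named list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  hasFiles <- !is.null(raw$matrixPath)
  hasSim <- !is.null(raw$simulation)
  if (hasFiles == hasSim)
    stop("config must contain exactly one of matrix/metadata paths or a ",
         "simulation block", call. = FALSE)
  cfg <- do.call(pipelineConfig, raw)
  if (hasFiles) cfg$simulation <- NULL
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.loadOrSimulateGfcr <- function(config) {
  if (!is.null(config$matrixPath)) {
    m <- readExpressionTsv(config$matrixPath)
    ann <- readSampleAnnotation(config$metadataPath)
    return(FractionExperiment(m, ann))
  }
  sim <- config$simulation
  design <- generateDesign(c("ileum", "colon"), c("tip", "crypt"),
                           c("GF", "CR"),
                           sim$replicatesGfcr %||% 5,
                           seed = config$seed)
  args <- sim[setdiff(names(sim), c("replicatesGfcr",
                                    "replicatesTimecourse", "days"))]
  do.call(simulateExpression, c(list(design = design), args))
}

#' Run the GF-versus-CR analysis end to end
#'
#' Simulates (or loads) the 2 tissue x 2 fraction x GF/CR expression matrix,
#' quantile-normalizes it, clusters the samples, runs the per-fraction
#' moderated t contrasts, partitions significant genes into the Venn
#' regions, and computes gene-set and regulator enrichment per fraction with
#' the empirical background, top-k selection and cross-fraction specificity.
#' With simulated input, gene sets and regulator target maps are generated
#' with planted truth and a recovery report is included.
#'
#' @param config List from [pipelineConfig()] / [readPipelineConfig()].
#' @param outDir Output directory; when non-NULL all declared outputs are
#'   written there (TSV/JSON/newick) together with a run manifest.
#' @return Invisible list with elements experiment, sampleTree, contrasts,
#'   venn, specificity, geneSetEnrichment, regulatorEnrichment, topRegulators,
#'   regulatorSpecificity and (simulation only) recovery.
#' @export
runGfVsCr <- function(config = pipelineConfig(), outDir = config$outDir) {
  fe <- .stage("input", .loadOrSimulateGfcr(config))
  message(sprintf("input: %d genes x %d samples", nrow(fe), ncol(fe)))
  fe <- .stage("normalize", quantileNormalize(log2IfNeeded(fe)))

  tree <- .stage("cluster-samples", hierarchicalCluster(
    pearsonDistance(assay(fe, "exprs"), margin = 2)))

  cd <- colData(fe)
  combos <- unique(data.frame(tissue = cd$tissue, fraction = cd$fraction))
  contrasts <- .stage("diffexp", {
    out <- lapply(seq_len(nrow(combos)), function(i)
      moderatedTContrast(fe, combos$tissue[i], combos$fraction[i]))
    names(out) <- .fractionKey(combos$tissue, combos$fraction)
    out
  })
  venn <- .stage("venn", significantSets(contrasts, alpha = config$alphaDE))
  spec <- specificitySummary(venn)
  message(sprintf("diffexp: %d regulated genes, %d%% fraction-specific",
                  spec$nTotal, spec$percentSpecific))

  universe <- rownames(fe)
  gt <- groundTruth(fe)
  lists <- vennSets(venn)
  regulatedUnion <- Reduce(union, lists)

  if (!is.null(gt)) {
    genesets <- .stage("genesets", generateGeneSets(
      universe, regulatedUnion, seed = childSeed(config$seed, 10L)))
    regTargets <- .stage("regulator-targets", .syntheticRegulators(
      universe, lists, seed = childSeed(config$seed, 11L)))
  } else {
    genesets <- if (!is.null(config$gmtPath)) readGmt(config$gmtPath) else
      NULL
    regTargets <- if (!is.null(config$targetsPath))
      geneSets(readGmt(config$targetsPath)) else NULL
  }

  gse <- regEnr <- NULL
  topReg <- regSpec <- NULL
  if (!is.null(genesets))
    gse <- .stage("geneset-enrichment", lapply(lists, geneSetEnrichment,
                                               collection = genesets,
                                               universe = universe,
                                               minMembers = config$minMembers,
                                               pCeiling = config$goPCeiling))
  if (!is.null(regTargets)) {
    regEnr <- .stage("regulator-enrichment", {
      out <- lapply(seq_along(lists), function(i)
        regulatorEnrichment(lists[[i]], regTargets, universe,
                            nDraws = config$backgroundDraws,
                            pCeiling = config$regulatorPCeiling,
                            seed = childSeed(config$seed, 20L + i)))
      names(out) <- names(lists)
      out
    })
    topReg <- topKRegulators(regEnr, k = config$topK)
    regSpec <- regulatorSpecificity(topReg$merged)
    message(sprintf(
      "regulators: %d unique in top-%d; %d%% shared, %d%% specific",
      regSpec$n, config$topK, regSpec$percentShared,
      regSpec$percentSpecific))
  }

  recovery <- if (!is.null(gt)) .gfcrRecovery(gt, venn) else NULL
  bundle <- list(experiment = fe, sampleTree = tree, contrasts = contrasts,
                 venn = venn, specificity = spec, geneSetEnrichment = gse,
                 regulatorEnrichment = regEnr, topRegulators = topReg,
                 regulatorSpecificity = regSpec, recovery = recovery,
                 geneSetsUsed = genesets)
  if (!is.null(outDir)) .writeGfcrOutputs(bundle, config, outDir)
  invisible(bundle)
}

## synthetic regulator target maps: one planted regulator per fraction
## covering half of that fraction's significant list, plus null regulators
.syntheticRegulators <- function(universe, lists, nNull = 120, seed = 1L) {
  set.seed(seed)
  targets <- list()
  for (key in names(lists)) {
    sig <- lists[[key]]
    nPick <- max(1L, floor(length(sig) / 2))
    core <- sample(sig, nPick)
    pad <- sample(setdiff(universe, core), nPick)
    targets[[paste0("REG_", key)]] <- c(core, pad)
  }
  sizes <- sample(50:500, nNull, replace = TRUE)
  for (i in seq_len(nNull))
    targets[[sprintf("REG_null%02d", i)]] <- sample(universe, sizes[i])
  targets
}

.gfcrRecovery <- function(gt, venn) {
  sets <- vennSets(venn)
  memb <- vapply(sets, function(s) gt@universe %in% s,
                 logical(length(gt@universe)))
  rownames(memb) <- gt@universe
  perFraction <- lapply(names(sets), function(key) {
    planted <- names(gt@regulated[[key]])
    if (!length(planted)) return(c(planted = 0, exclusive = 0))
    exclusive <- memb[planted, key] & rowSums(memb[planted, , drop = FALSE]) == 1L
    c(planted = length(planted), exclusive = sum(exclusive))
  })
  names(perFraction) <- names(sets)
  tot <- Reduce(`+`, perFraction)
  list(perFraction = perFraction,
       exclusiveRecoveryRate = unname(tot["exclusive"] / tot["planted"]))
}

.writeGfcrOutputs <- function(bundle, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeExpressionTsv(bundle$experiment, file.path(outDir,
                                                  "expression_normalized.tsv"))
  writeSampleAnnotation(as.data.frame(colData(bundle$experiment)),
                        file.path(outDir, "sample_metadata.tsv"))
  writeNewick(bundle$sampleTree, file.path(outDir, "sample_dendrogram.nwk"))
  for (key in names(bundle$contrasts)) {
    tab <- contrastTable(bundle$contrasts[[key]])
    tab$significant <- tab$pAdj < config$alphaDE
    data.table::fwrite(tab, file.path(outDir,
                                      sprintf("contrast_%s.tsv", key)),
                       sep = "\t", quote = FALSE)
  }
  jsonlite::write_json(
    list(regions = as.list(vennRegions(bundle$venn)),
         specificity = bundle$specificity),
    file.path(outDir, "venn_partition.json"), auto_unbox = TRUE, digits = NA)
  for (key in names(bundle$geneSetEnrichment %||% list()))
    data.table::fwrite(enrichmentTable(bundle$geneSetEnrichment[[key]]),
                       file.path(outDir, sprintf("go_enrichment_%s.tsv", key)),
                       sep = "\t", quote = FALSE)
  for (key in names(bundle$regulatorEnrichment %||% list()))
    data.table::fwrite(enrichmentTable(bundle$regulatorEnrichment[[key]]),
                       file.path(outDir,
                                 sprintf("regulator_enrichment_%s.tsv", key)),
                       sep = "\t", quote = FALSE)
  manifest <- list(
    config = config[setdiff(names(config), "outDir")],
    package = as.character(utils::packageVersion("EpiFractions")),
    rVersion = R.version.string)
  cfgJson <- jsonlite::toJSON(manifest$config, auto_unbox = TRUE, digits = NA)
  tmp <- file.path(outDir, "config.json")
  writeLines(cfgJson, tmp)
  manifest$configHash <- unname(tools::md5sum(tmp))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}

#' Run the colonization time-course analysis end to end
#'
#' Simulates (or loads) the day-structured experiment, normalizes it, and
#' per (tissue, fraction) compartment applies the one-way ANOVA gate,
#' consensus-clusters the gated genes' replicate-averaged day profiles,
#' selects the number of clusters, and summarizes per-cluster mean +/- sd
#' trajectories.  Cluster members are additionally partitioned across
#' fractions to quantify how many cluster-1 genes are fraction-specific.
#'
#' @param config List from [pipelineConfig()]; the simulation block uses
#'   `replicatesTimecourse` replicates over days 0, 1, 3, 5, 7.
#' @param truth Optional [GroundTruth-class] to reuse (e.g. from a GF/CR
#'   run); by default a fresh GF/CR simulation provides the regulated-gene
#'   truth.
#' @param outDir Output directory (as in [runGfVsCr()]).
#' @return Invisible list with experiment, per-compartment gate, consensus,
#'   profiles, and the cluster-1 cross-fraction partition.
#' @export
runColonization <- function(config = pipelineConfig(), truth = NULL,
                            outDir = config$outDir) {
  sim <- config$simulation
  if (is.null(sim) && is.null(config$matrixPath))
    stop("config must provide either a simulation block or input paths",
         call. = FALSE)
  if (!is.null(config$matrixPath)) {
    fe <- .stage("input", FractionExperiment(
      readExpressionTsv(config$matrixPath),
      readSampleAnnotation(config$metadataPath)))
  } else {
    design <- generateDesign(c("ileum", "colon"), c("tip", "crypt"),
                             as.character(sim$days %||% c(0, 1, 3, 5, 7)),
                             sim$replicatesTimecourse %||% 3,
                             seed = config$seed)
    if (length(design@conditions) < 2L)
      stop("[stage input] time course needs more than one day",
           call. = FALSE)
    if (is.null(truth)) {
      gfcrDesign <- generateDesign(c("ileum", "colon"), c("tip", "crypt"),
                                   c("GF", "CR"), 5, seed = config$seed)
      truth <- groundTruth(simulateExpression(
        gfcrDesign, nGenes = sim$nGenes %||% 20000))
    }
    fe <- .stage("simulate", simulateTimecourse(design, truth))
  }
  if (length(unique(colData(fe)$day)) < 2L)
    stop("[stage input] time course needs more than one day", call. = FALSE)
  fe <- .stage("normalize", quantileNormalize(log2IfNeeded(fe)))

  cd <- colData(fe)
  combos <- unique(data.frame(tissue = cd$tissue, fraction = cd$fraction))
  keys <- .fractionKey(combos$tissue, combos$fraction)
  gates <- list(); consensus <- list(); profiles <- list()
  for (i in seq_len(nrow(combos))) {
    key <- keys[i]
    sel <- cd$tissue == combos$tissue[i] & cd$fraction == combos$fraction[i]
    m <- assay(fe, "exprs")[, sel, drop = FALSE]
    day <- cd$day[sel]
    gate <- .stage(paste0("anova-gate:", key),
                   anovaGate(m, day, alpha = config$alphaGate))
    message(sprintf("%s: %d genes pass the ANOVA gate", key,
                    length(gatedGenes(gate))))
    prof <- dayProfiles(m[gatedGenes(gate), , drop = FALSE], day)
    cons <- .stage(paste0("consensus:", key),
                   consensusCluster(prof, kRange = config$kRange,
                                    nResamples = config$nResamples,
                                    subsampleFraction =
                                      config$subsampleFraction,
                                    seed = childSeed(config$seed, 30L + i)))
    message(sprintf("%s: chosen K = %d", key, chosenK(cons)))
    cons@profiles <- clusterProfiles(clusterAssignment(cons), m, day)
    gates[[key]] <- gate; consensus[[key]] <- cons
    profiles[[key]] <- cons@profiles
  }

  cluster1Sets <- lapply(consensus, function(cons) {
    a <- clusterAssignment(cons)
    ## cluster "1" per compartment = the strongest-increase cluster: largest
    ## late-vs-early mean profile change
    pr <- cons@profiles
    up <- vapply(split(pr, pr$cluster), function(d)
      d$mean[which.max(d$day)] - d$mean[which.min(d$day)], numeric(1))
    names(a)[a == as.integer(names(which.max(up)))]
  })
  cluster1Venn <- if (length(cluster1Sets) >= 2L)
    significantSets(cluster1Sets) else NULL
  cluster1Spec <- if (!is.null(cluster1Venn))
    specificitySummary(cluster1Venn) else NULL

  bundle <- list(experiment = fe, gates = gates, consensus = consensus,
                 profiles = profiles, cluster1Partition = cluster1Venn,
                 cluster1Specificity = cluster1Spec)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(consensus)) {
      data.table::fwrite(
        data.frame(gene = names(clusterAssignment(consensus[[key]])),
                   cluster = clusterAssignment(consensus[[key]])),
        file.path(outDir, sprintf("clusters_%s.tsv", key)),
        sep = "\t", quote = FALSE)
      data.table::fwrite(profiles[[key]],
                         file.path(outDir,
                                   sprintf("cluster_profiles_%s.tsv", key)),
                         sep = "\t", quote = FALSE)
    }
    jsonlite::write_json(
      lapply(consensus, function(x) chosenK(x)),
      file.path(outDir, "chosen_k.json"), auto_unbox = TRUE)
  }
  invisible(bundle)
}
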