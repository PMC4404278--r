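test_that("generateDesign builds the crossed layouts and rejects bad input", {
  d <- gfcrDesign()
  expect_equal(nrow(designTable(d)), 40)
  expect_equal(nrow(designTable(generateDesign("ileum", "tip",
                                               c("GF", "CR"), 2))), 4)
  expect_equal(nrow(designTable(timecourseDesign())), 60)
  # 40 + 60 arrays reproduce the full study's hybridization count
  expect_equal(nrow(designTable(gfcrDesign())) +
                 nrow(designTable(timecourseDesign())), 100)
  expect_false(anyDuplicated(designTable(d)$sample) > 0)
  expect_error(generateDesign(c("ileum", "ileum"), "tip", c("GF", "CR"), 2),
               "duplicate")
  expect_error(generateDesign("ileum", "tip", c("GF", "CR"), 1),
               "replicatesPerGroup")
  # deterministic given arguments
  expect_identical(designTable(gfcrDesign()), designTable(gfcrDesign()))
})

test_that("simulateExpression plants effects where the truth says", {
  d <- gfcrDesign()
  fe <- simulateExpression(d, nGenes = 2000, seed = 11)
  expect_s4_class(fe, "FractionExperiment")
  expect_equal(dim(fe), c(2000L, 40L))
  gt <- groundTruth(fe)
  nReg <- sum(lengths(gt@regulated))
  expect_equal(nReg / 2000, 0.1, tolerance = 0.01)
  # regulated genes are a subset of the universe (validity) and the
  # fraction-specific share matches the requested rates
  expect_equal(sum(lengths(gt@regulated[setdiff(names(gt@regulated),
                                                "shared")])) / nReg,
               0.86, tolerance = 0.02)

  # the planted effect shows up as the CR-GF group-mean difference
  cd <- SummarizedExperiment::colData(fe)
  m <- SummarizedExperiment::assay(fe, "exprs")
  key <- "ileum_tip"
  sel <- cd$tissue == "ileum" & cd$fraction == "tip"
  eff <- gt@regulated[[key]]
  est <- rowMeans(m[names(eff), sel & cd$status == "CR", drop = FALSE]) -
    rowMeans(m[names(eff), sel & cd$status == "GF", drop = FALSE])
  expect_equal(unname(est), unname(eff), tolerance = 1)  # noise 0.4, n=5
  # and is absent in the other compartments
  selOther <- cd$tissue == "colon" & cd$fraction == "crypt"
  estOther <- rowMeans(m[names(eff), selOther & cd$status == "CR"]) -
    rowMeans(m[names(eff), selOther & cd$status == "GF"])
  expect_lt(max(abs(estOther)), 1.5)
})

test_that("simulateExpression null model is calibrated and reproducible", {
  d <- gfcrDesign()
  fe0 <- simulateExpression(d, nGenes = 6000, fractionSpecificRate = 0,
                            sharedRate = 0, seed = 3)
  expect_true(all(lengths(groundTruth(fe0)@regulated) == 0))
  cd <- SummarizedExperiment::colData(fe0)
  m <- SummarizedExperiment::assay(fe0, "exprs")
  sel <- cd$tissue == "ileum" & cd$fraction == "tip"
  p <- pooledTPvalues(m, which(sel & cd$status == "CR"),
                      which(sel & cd$status == "GF"))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)

  # determinism: same arguments + seed give bit-identical output
  fe0b <- simulateExpression(d, nGenes = 6000, fractionSpecificRate = 0,
                             sharedRate = 0, seed = 3)
  expect_identical(SummarizedExperiment::assay(fe0, "exprs"),
                   SummarizedExperiment::assay(fe0b, "exprs"))

  # with zero mean effect, group means deviate from baseline by O(sd/sqrt(n))
  feZ <- simulateExpression(d, nGenes = 1000, effectSizeMean = 0,
                            noiseSd = 1, tissueEffectSd = 0,
                            fractionEffectSd = 0, seed = 4)
  mz <- SummarizedExperiment::assay(feZ, "exprs")
  cdz <- SummarizedExperiment::colData(feZ)
  grp <- mz[, cdz$tissue == "ileum" & cdz$fraction == "tip" &
                cdz$status == "GF"]
  dev <- rowMeans(grp) - rowMeans(mz)
  expect_equal(sd(dev), 1 / sqrt(5), tolerance = 0.25)
  expect_error(simulateExpression(d, nGenes = 50), "nGenes")
  expect_error(simulateExpression(d, nGenes = 200, noiseSd = 0), "noiseSd")
  expect_error(simulateExpression(d, nGenes = 200,
                                  fractionSpecificRate = 0.9,
                                  sharedRate = 0.2), "sum")
})

test_that("simulateTimecourse follows the archetype trajectories", {
  dt <- timecourseDesign()
  dg <- gfcrDesign()
  gt <- groundTruth(simulateExpression(dg, nGenes = 1000, seed = 5))
  # noiseSd = 0: replicate-averaged profiles equal baseline + archetype shape
  fe <- simulateTimecourse(dt, gt, noiseSd = 1e-12, seed = 6)
  gt2 <- groundTruth(fe)
  cd <- SummarizedExperiment::colData(fe)
  m <- SummarizedExperiment::assay(fe, "exprs")
  for (key in c("ileum_tip", "colon_crypt")) {
    tis <- strsplit(key, "_")[[1]][1]
    sel <- cd$tissue == tis &
      cd$fraction == strsplit(key, "_")[[1]][2]
    prof <- dayProfiles(m[, sel, drop = FALSE], cd$day[sel])
    shapes <- defaultArchetypeShapes(tis)
    a <- gt2@clusterAssignments[[key]]
    for (g in names(a)[seq_len(min(5, length(a)))]) {
      centered <- prof[g, ] - prof[g, "0"]
      expect_equal(unname(centered),
                   unname(shapes[a[[g]], ] - shapes[a[[g]], 1]),
                   tolerance = 1e-6)
    }
  }
  # ileum-like kinetics step between day 3 and 5; colon-like between 1 and 3
  shI <- defaultArchetypeShapes("ileum"); shC <- defaultArchetypeShapes("colon")
  expect_equal(unname(shI[1, ]), c(0, 0, 0, 2, 2))
  expect_equal(unname(shC[1, ]), c(0, 0, 2, 2, 2))
  expect_error(simulateTimecourse(dt, gt, archetypeShapes = list()),
               "archetype shapes")
  expect_error(simulateTimecourse(dg, gt), "day-structured")
})

test_that("flat time-course genes pass a per-gene ANOVA at the nominal rate", {
  dt <- timecourseDesign()
  gt <- new("GroundTruth", universe = sprintf("g%05d", 1:2000))
  fe <- simulateTimecourse(dt, gt, seed = 8)  # nothing regulated: all flat
  cd <- SummarizedExperiment::colData(fe)
  sel <- cd$tissue == "ileum" & cd$fraction == "tip"
  gate <- anovaGate(SummarizedExperiment::assay(fe, "exprs")[, sel],
                    cd$day[sel], alpha = 0.05)
  frac <- mean(gate@table$pRaw > 0.05)
  expect_equal(frac, 0.95, tolerance = 0.02)
})

test_that("generateGeneSets plants enrichment and honors the size filter", {
  u <- sprintf("g%05d", 1:2000)
  set.seed(1); reg <- sample(u, 200)
  gs <- generateGeneSets(u, reg, nTerms = 60, nEnriched = 5,
                         termSizeRange = c(6, 200),
                         enrichmentStrength = 1, seed = 2)
  enr <- attr(gs, "enriched")
  expect_length(enr, 5)
  for (id in enr)
    expect_true(all(geneSets(gs)[[id]] %in% reg))
  expect_true(all(lengths(geneSets(gs)) > 5))

  # strength 0: overlap with the regulated list follows the hypergeometric law
  gs0 <- generateGeneSets(u, reg, nTerms = 400, nEnriched = 400,
                          termSizeRange = c(50, 50),
                          enrichmentStrength = 0, seed = 3)
  ks <- vapply(geneSets(gs0), function(s) length(intersect(s, reg)),
               numeric(1))
  expMean <- 50 * 200 / 2000
  expVar <- 50 * (200 / 2000) * (1800 / 2000) * (1950 / 1999)
  expect_equal(mean(ks), expMean, tolerance = 3 * sqrt(expVar / 400) /
                 expMean)
  expect_equal(var(ks), expVar, tolerance = 0.25)
  expect_error(generateGeneSets(u, reg, nTerms = 0), "nTerms")
  expect_error(generateGeneSets(u, reg, termSizeRange = c(10, 3000)),
               "universe")
})

test_that("generatePromoters writes 1 kb records and records plantings", {
  u <- sprintf("g%05d", 1:30)
  m1 <- toyMotif()
  pr <- generatePromoters(u, list(m1), plantingPlan = list(M1 = u[1:8]),
                          seed = 5)
  expect_true(all(Biostrings::width(pr$promoters) == 1000))
  expect_equal(nrow(pr$planted), 8)
  # substring oracle: the consensus (or its reverse complement) sits at the
  # recorded 0-based position
  seqs <- as.character(pr$promoters)
  cons <- consensusSequence(m1)
  for (i in seq_len(nrow(pr$planted))) {
    found <- unname(substr(seqs[pr$planted$gene[i]], pr$planted$start[i] + 1,
                           pr$planted$start[i] + nchar(cons)))
    expect_equal(found,
                 if (pr$planted$strand[i] == "+") cons else revcompChar(cons))
  }
  empty <- generatePromoters(u, list(m1), plantingPlan = list(), seed = 5)
  expect_equal(nrow(empty$planted), 0)
  expect_error(generatePromoters(u, list(m1), promoterLength = 5), "longer")
})

test_that("simulateQpcr encodes fold changes as Ct shifts", {
  d <- gfcrDesign()
  ct <- simulateQpcr(d, c(Pigr = 2), noiseSd = 0)
  dd <- deltaDeltaCt(ct, "Pigr")
  expect_equal(unique(dd$ddCt[dd$status == "CR"]), -1)
  expect_equal(unique(dd$fold[dd$status == "GF"]), 1)
  # per-group replicate counts match the design
  counts <- table(ct$tissue, ct$fraction, ct$status)[, , "CR"] /
    length(unique(ct$gene))
  expect_true(all(counts == 5))
  # fold ~ 1 recovered on average under the null
  ct1 <- simulateQpcr(d, c(G = 1), noiseSd = 0.2, seed = 9)
  dd1 <- deltaDeltaCt(ct1, "G")
  expect_equal(mean(dd1$fold[dd1$status == "CR"]), 1, tolerance = 0.1)
  expect_error(simulateQpcr(d, c(Pigr = -1)), "positive")
})
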