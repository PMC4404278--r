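test_that("Pearson distance behaves as 1 - r", {
  x <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1),
             d = c(1, 2, 4))
  d <- pearsonDistance(x, margin = 1)
  expect_equal(d["a", "b"], 0)            # identical up to scale
  expect_equal(d["a", "c"], 2)            # exactly anti-correlated
  expect_equal(d["a", "d"], 1 - cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(d["a", "d"], 1 - 0.98198, tolerance = 1e-3)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  xc <- rbind(x, e = c(5, 5, 5))
  expect_error(pearsonDistance(xc, margin = 1), "e")
})

test_that("hierarchical clustering matches a brute-force average-linkage oracle", {
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  hc2 <- hierarchicalCluster(d2)
  expect_equal(hc2$height, 0.7)

  d3 <- matrix(1, 3, 3); diag(d3) <- 0; d3[1, 2] <- d3[2, 1] <- 0.1
  dimnames(d3) <- list(LETTERS[1:3], LETTERS[1:3])
  hc3 <- hierarchicalCluster(d3)
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))  # A,B merge first

  set.seed(21)
  for (i in 1:5) {
    n <- 8
    m <- matrix(runif(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    hc <- hierarchicalCluster(m)
    oracle <- bruteForceAverageLinkage(m)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    expect_equal(as.matrix(cophenetic(hc))[letters[1:n], letters[1:n]],
                 oracle$cophenetic, ignore_attr = TRUE, tolerance = 1e-12)
  }
  dn <- d3; dn[1, 3] <- NA
  expect_error(hierarchicalCluster(dn), "NA")
})

test_that("sample dendrogram separates fraction, then tissue, then status", {
  fe <- simulateExpression(gfcrDesign(), nGenes = 3000, seed = 17)
  m <- SummarizedExperiment::assay(quantileNormalize(fe), "exprs")
  cd <- SummarizedExperiment::colData(fe)
  hc <- hierarchicalCluster(pearsonDistance(m, margin = 2))
  # the first split separates the fractions, the 4-cut the compartments
  k2 <- cutree(hc, 2)
  expect_equal(length(unique(tapply(k2, cd$fraction, function(x)
    paste(sort(unique(x)), collapse = "")))), 2)
  k4 <- cutree(hc, 4)
  key <- paste(cd$tissue, cd$fraction)
  expect_true(all(tapply(k4, key, function(x) length(unique(x))) == 1))
  # within a compartment, statuses separate only deeper in the tree
  coph <- as.matrix(cophenetic(hc))
  sameComp <- outer(key, key, "==")
  sameFrac <- outer(as.character(cd$fraction), as.character(cd$fraction),
                    "==")
  offDiag <- row(coph) != col(coph)
  expect_lt(mean(coph[sameComp & offDiag]), mean(coph[!sameFrac]))
})

test_that("the ANOVA gate is a classical one-way F-test", {
  set.seed(5)
  day <- rep(c(0, 1, 3, 5, 7), each = 3)
  m <- matrix(rnorm(5 * 15), 5, 15,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:15)))
  gate <- anovaGate(m, day, alpha = 0.05)
  for (i in 1:5) {
    ref <- anova(lm(m[i, ] ~ factor(day)))
    expect_equal(gate@table$F[i], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(gate@table$pRaw[i], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  # two groups: F = t^2
  day2 <- rep(c(0, 7), each = 4)
  m2 <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(paste0("g", 1:3), NULL))
  gate2 <- anovaGate(m2, day2, alpha = 0.05)
  for (i in 1:3) {
    tt <- t.test(m2[i, day2 == 0], m2[i, day2 == 7], var.equal = TRUE)
    expect_equal(gate2@table$F[i], unname(tt$statistic)^2,
                 tolerance = 1e-10)
  }

  # null p-values are uniform
  set.seed(6)
  mn <- matrix(rnorm(5000 * 15), 5000, 15,
               dimnames = list(sprintf("g%04d", 1:5000), NULL))
  gn <- anovaGate(mn, day, alpha = 0.001)
  expect_gt(ks.test(gn@table$pRaw, "punif")$p.value, 0.01)

  # a strong step gene is gated in nearly all replicate draws
  set.seed(7)
  hits <- vapply(1:200, function(i) {
    y <- rbind(step = ifelse(day >= 5, 2, 0) + rnorm(15, 0, 0.3))
    rownames(y) <- "step"
    anovaGate(y, day, alpha = 0.001)@table$pRaw < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.97)

  expect_error(anovaGate(m, rep(c(0, 1, 3, 5, 7), c(1, 2, 3, 4, 5))),
               "two replicates")
  expect_error(anovaGate(m, rep(0, 15)), "two time points")
})

test_that("consensus clustering resolves planted structure", {
  # two point-mass shape clusters: consensus is an exact 0/1 block matrix
  prof <- rbind(matrix(rep(c(0, 0, 0, 2, 2), each = 10), 10),
                matrix(rep(c(2, 2, 0, 0, 0), each = 10), 10))
  prof <- prof + matrix(rnorm(100, 0, 1e-6), 20)
  rownames(prof) <- sprintf("g%02d", 1:20)
  cons <- consensusCluster(prof, kRange = 2, nResamples = 50, seed = 3)
  cm <- consensusMatrix(cons, 2)
  blocks <- clusterAssignment(cons)
  expect_equal(chosenK(cons), 2L)
  same <- outer(blocks, blocks, "==")
  expect_true(all(cm[same] == 1))
  expect_true(all(cm[!same] == 0))

  # relabeling genes leaves consensus values untouched (same order/seed)
  prof2 <- prof
  rownames(prof2) <- sprintf("x%02d", 1:20)
  cons2 <- consensusCluster(prof2, kRange = 2, nResamples = 50, seed = 3)
  expect_equal(unname(consensusMatrix(cons2, 2)), unname(cm))

  expect_error(consensusCluster(prof, kRange = 2:10), "kRange")
})

test_that("archetype recovery: K = 4 and high agreement with the truth", {
  skip_if_not_installed("mclust")
  gt <- groundTruth(simulateExpression(gfcrDesign(), nGenes = 3000,
                                       seed = 23))
  fe <- simulateTimecourse(timecourseDesign(), gt, seed = 24)
  cd <- SummarizedExperiment::colData(fe)
  gt2 <- groundTruth(fe)
  for (key in c("ileum_tip", "colon_crypt")) {
    parts <- strsplit(key, "_")[[1]]
    sel <- cd$tissue == parts[1] & cd$fraction == parts[2]
    m <- SummarizedExperiment::assay(fe, "exprs")[, sel]
    gate <- anovaGate(m, cd$day[sel])
    prof <- dayProfiles(m[gatedGenes(gate), ], cd$day[sel])
    cons <- consensusCluster(prof, seed = 25)
    expect_equal(chosenK(cons), 4L)
    a <- clusterAssignment(cons)
    planted <- gt2@clusterAssignments[[key]]
    common <- intersect(names(a), names(planted))
    expect_gt(length(common), 50)
    expect_gte(mclust::adjustedRandIndex(a[common], planted[common]), 0.9)
  }
})

test_that("cluster profiles summarize member trajectories", {
  set.seed(9)
  day <- rep(c(0, 1, 3, 5, 7), each = 2)
  m <- matrix(rnorm(6 * 10, 5, 0.1), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  m["g1", ] <- m["g1", ] + ifelse(day >= 5, 3, 0)
  assignment <- c(g1 = 1L, g2 = 2L, g3 = 2L, g4 = 2L, g5 = 2L, g6 = 2L)
  pr <- clusterProfiles(assignment, m, day)
  expect_equal(sum(pr$n[!duplicated(pr$cluster)]), 6)
  expect_equal(pr$sd[pr$cluster == 1], rep(0, 5))  # single-gene cluster
  m1 <- pr$mean[pr$cluster == 1]
  expect_gt(m1[4] - m1[1], 2.5)
  # per-day means equal the replicate-averaged member mean
  profs <- dayProfiles(m[names(assignment)[assignment == 2], ], day)
  expect_equal(pr$mean[pr$cluster == 2], unname(colMeans(profs)))
  expect_error(clusterProfiles(c(zz = 1L), m, day), "absent")
})
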