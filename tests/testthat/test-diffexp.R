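test_that("variance prior recovers known hyperparameters", {
  # equal variances: no dispersion, d0 infinite
  prEq <- suppressWarnings(fitVariancePrior(rep(2, 100), dg = 8))
  expect_equal(priorDf(prEq), Inf)
  expect_equal(priorVar(prEq), 2)

  # parameter recovery: gene variances from the scaled-F model with
  # d0 = 4, s0sq = 1 (truth drawn, then chi-squared residual sampling)
  set.seed(42)
  trueVar <- 1 * 4 / rchisq(20000, df = 4)
  obs <- trueVar * rchisq(20000, 8) / 8
  pr <- fitVariancePrior(obs, 8)
  expect_gt(priorDf(pr), 3.5); expect_lt(priorDf(pr), 4.5)
  expect_gt(priorVar(pr), 0.95); expect_lt(priorVar(pr), 1.05)

  expect_warning(fitVariancePrior(rchisq(10, 4), 8), "fewer than 50")
  expect_error(suppressWarnings(fitVariancePrior(rep(0, 60), 8)), "zero")
})

test_that("variance prior matches the independent reference fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  obs <- (2 * 5 / rchisq(5000, 5)) * rchisq(5000, 6) / 6
  pr <- fitVariancePrior(obs, 6)
  ref <- limma::fitFDist(obs, df1 = 6)
  expect_equal(priorDf(pr), ref$df2, tolerance = 1e-8)
  expect_equal(priorVar(pr), ref$scale, tolerance = 1e-8)
})

test_that("moderated t follows its formula and limits", {
  # hand case: md = 2, s2Post = 1, n = 5 vs 5 -> t = 2/sqrt(0.4) = 3.1623
  prior <- new("ModeratedTPrior", d0 = 4, s0sq = 1)
  m <- cbind(matrix(10, 2, 5), matrix(8, 2, 5))
  dimnames(m) <- list(c("gA", "gB"), paste0("s", 1:10))
  # zero within-group variance: s2 = 0, s2Post = d0*s0sq/(d0+dg) = 4/12
  cr <- moderatedTContrast(m, groupA = 1:5, groupB = 6:10, prior = prior)
  s2post <- 4 * 1 / (4 + 8)
  expect_equal(contrastTable(cr)$t,
               rep(2 / sqrt(s2post * 0.4), 2))
  expect_equal(contrastTable(cr)$df, rep(12, 2))

  set.seed(1)
  r <- matrix(rnorm(2000, 0, 1), 200, 10,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:10)))
  # d0 -> 0 limit equals the ordinary pooled t
  tiny <- new("ModeratedTPrior", d0 = 1e-8, s0sq = 1)
  crT <- moderatedTContrast(r, 1:5, 6:10, prior = tiny)
  expect_equal(contrastTable(crT)$pRaw,
               unname(pooledTPvalues(r, 1:5, 6:10)), tolerance = 1e-6)

  # d0 = Inf: a z-like statistic using s0sq only
  inf <- new("ModeratedTPrior", d0 = Inf, s0sq = 0.5)
  crI <- moderatedTContrast(r, 1:5, 6:10, prior = inf)
  md <- rowMeans(r[, 1:5]) - rowMeans(r[, 6:10])
  expect_equal(contrastTable(crI)$t, unname(md / sqrt(0.5 * 0.4)))
  expect_equal(contrastTable(crI)$pRaw,
               unname(2 * pnorm(-abs(md / sqrt(0.5 * 0.4)))))

  expect_error(moderatedTContrast(r, 1:1, 6:10), "two samples")
  expect_error(moderatedTContrast(r, 1:5, 5:10), "disjoint")
})

test_that("moderated t agrees with the reference pipeline", {
  skip_if_not_installed("limma")
  set.seed(3)
  m <- matrix(rnorm(500 * 10), 500,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:10)))
  m <- m * sqrt(2 / rchisq(500, 4) * 2)  # heterogeneous gene variances
  m[1:50, 6:10] <- m[1:50, 6:10] + 1
  cr <- moderatedTContrast(m, groupA = 6:10, groupB = 1:5)
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(0:1, each = 5))))
  expect_equal(contrastTable(cr)$t, unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(contrastTable(cr)$pRaw, unname(fit$p.value[, 2]),
               tolerance = 1e-6)
  expect_equal(priorDf(cr), fit$df.prior, tolerance = 1e-8)
})

test_that("null contrasts control the raw type-I rate at 0.001", {
  set.seed(11)
  r <- matrix(rnorm(10000 * 10), 10000, 10,
              dimnames = list(sprintf("g%05d", 1:10000), paste0("s", 1:10)))
  cr <- moderatedTContrast(r, 1:5, 6:10)
  frac <- mean(contrastTable(cr)$pRaw < 0.001)
  expect_gte(frac, 0.0005); expect_lte(frac, 0.002)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjaminiHochberg(0.37), 0.37)
  set.seed(13)
  for (i in 1:1000) {
    p <- runif(sample(1:60, 1))
    expect_equal(benjaminiHochberg(p), bruteForceBH(p))
  }
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Venn partitioning enumerates regions correctly", {
  v <- significantSets(list(f1 = c("a", "b"), f2 = c("b", "c"),
                            f3 = character(), f4 = character()))
  reg <- vennRegions(v)
  expect_equal(unname(reg[c("f1", "f2", "f3", "f4")]), c(1, 1, 0, 0))
  expect_equal(unname(reg[["f1+f2"]]), 1)
  expect_equal(length(v@universe), 3)
  expect_equal(sum(reg), 3)

  same <- replicate(4, letters[1:5], simplify = FALSE)
  names(same) <- paste0("f", 1:4)
  v2 <- significantSets(same)
  expect_equal(unname(vennRegions(v2)[["f1+f2+f3+f4"]]), 5)
  expect_equal(sum(vennRegions(v2)), 5)

  # from ContrastResults, thresholding adjusted p at alpha
  set.seed(2)
  mats <- lapply(1:2, function(i) {
    m <- matrix(rnorm(3000), 300, 10,
                dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:10)))
    m[i * 10 + 1:10, 1:5] <- m[i * 10 + 1:10, 1:5] + 4
    m
  })
  crs <- lapply(mats, moderatedTContrast, groupA = 1:5, groupB = 6:10)
  names(crs) <- c("fA", "fB")
  v3 <- significantSets(crs, alpha = 0.001)
  expect_setequal(vennSets(v3)$fA,
                  contrastTable(crs$fA)$gene[contrastTable(crs$fA)$pAdj <
                                               0.001])
  # mismatched universes are rejected
  crs$fB@table$gene[1] <- "zzz"
  expect_error(significantSets(crs), "universe")
})

test_that("specificity summary reproduces the published arithmetic", {
  s <- specificitySummary(c(340, 894, 273, 444), total = 2256)
  expect_equal(s$nSpecific, 1951L)
  expect_equal(s$percentSpecific, 86L)

  allShared <- significantSets(replicate(4, c("x", "y"), simplify = FALSE) |>
                                 setNames(paste0("f", 1:4)))
  expect_equal(specificitySummary(allShared)$percentSpecific, 0L)
  allExcl <- significantSets(list(f1 = "a", f2 = "b", f3 = "c", f4 = "d"))
  expect_equal(specificitySummary(allExcl)$percentSpecific, 100L)
  expect_true(is.na(specificitySummary(numeric(4), total = 0)$percentSpecific))
})
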