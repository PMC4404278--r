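# EpiFractions

Site-specific microbiota-induced transcriptional responses in intestinal
epithelial fractions.

## What this package is for

The gut microbiota rewrites a substantial part of the intestinal
epithelium's transcriptome, and it does so compartment by compartment:
differentiated **tip** and proliferative **crypt** cells of the **ileum**
and the proximal **colon** each respond differently.  EpiFractions is an
analysis pipeline for expression studies built on that design —
laser-capture-microdissected epithelial fractions from germ-free (GF)
versus conventionally raised (CR) mice, and the same four compartments
followed through a colonization time course (days 0, 1, 3, 5, 7).  It is
aimed at computational biologists who want the complete downstream
analysis of such data as tested, reusable functions rather than a one-off
script stack.

The pipeline covers:

* **Quantile normalization** and log-scale detection for summarized
  probe-set × sample matrices.
* **Per-compartment differential expression** by empirical-Bayes moderated
  t-test: per-gene variances `s²_g` (df `d_g`) are shrunk toward a prior
  `(d₀, s₀²)` fitted by moment-matching `log s²_g` under a scaled-F model,

  ```
  s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g)
  t̃_g  = (ȳ_CR − ȳ_GF) / sqrt(s̃²_g · (1/n_CR + 1/n_GF)),  df = d₀ + d_g
  ```

  with Benjamini–Hochberg correction and the headline gate at adjusted
  p < 0.001.
* **Fraction-specificity partitioning**: Venn regions over the four
  per-compartment significant sets, with the exclusive (single-compartment)
  share summarized as a rounded percentage.
* **Time-course consensus clustering**: one-way ANOVA gate (adjusted
  p < 0.001), then subsampling consensus clustering of z-scored day
  profiles under Pearson correlation distance, with the number of clusters
  chosen by the consensus-CDF delta-area rule.
* **Enrichment**: hypergeometric over-representation for GO-style gene
  sets (filters: adjusted p < 1e-5, more than 5 overlap members) and
  regulator/miRNA target maps tested against an **empirical background**
  — the mean Fisher p of 1,000 random gene lists of the same size — with
  top-50-per-compartment selection and cross-compartment sharing counts.
* **Promoter motif scanning**: log2-odds PWM scores over both strands of
  1 kb promoters, threshold as a fraction of the maximum attainable score.
* **qPCR quantification**: ΔΔCt relative expression (`2^−ΔΔCt`, L32
  reference, GF calibrator per compartment) and two-way ANOVA
  (status × fraction, Type-II sums of squares).
* **Synthetic data with ground truth** emulating the study design (40
  GF/CR arrays, 60 time-course arrays, ~10% regulated genes of which 86%
  compartment-specific, four trajectory archetypes with faster colonic
  kinetics), so every stage's recovery is testable.

Everything is exposed Bioconductor-style: S4 classes with validity
(`FractionExperiment` extends `SummarizedExperiment`; `ContrastResult`,
`VennPartition`, `ConsensusResult`, `EnrichmentResult`, `MotifMatrix`,
`GroundTruth`), accessor generics, and camelCase functions.

## Worked example

```r
library(EpiFractions)

design <- generateDesign(c("ileum", "colon"), c("tip", "crypt"),
                         c("GF", "CR"), 5, seed = 1)
design
#> StudyDesign: 2 tissues x 2 fractions x 2 status levels x 5 replicates = 40 samples

fe <- quantileNormalize(simulateExpression(design, nGenes = 8000, seed = 2))

contrast <- moderatedTContrast(fe, "ileum", "tip")
contrast
#> ContrastResult 'ileum_tip': 8000 genes, n = 5 vs 5, prior d0 = Inf
head(contrastTable(contrast)[order(contrastTable(contrast)$pAdj), ], 3)
#>        gene  meanDiff        s2    s2Post         t  df         pRaw         pAdj
#> 7544 g07544  4.294827 0.1419458 0.1618027  16.88196 Inf 6.108378e-64 4.886703e-60
#> 5367 g05367  3.810424 0.1941141 0.1618027  14.97788 Inf 1.024273e-50 4.097091e-47
#> 5013 g05013 -3.589623 0.2708848 0.1618027 -14.10997 Inf 3.297316e-45 6.594631e-42

cd <- SummarizedExperiment::colData(fe)
combos <- unique(data.frame(tissue = cd$tissue, fraction = cd$fraction))
contrasts <- lapply(seq_len(4), function(i)
  moderatedTContrast(fe, combos$tissue[i], combos$fraction[i]))
names(contrasts) <- paste(combos$tissue, combos$fraction, sep = "_")

venn <- significantSets(contrasts, alpha = 0.001)
venn
#> VennPartition over 4 fractions: union 771 genes; exclusives: ileum_tip=166,
#>   ileum_crypt=135, colon_tip=184, colon_crypt=176
specificitySummary(venn)
#> $nSpecific [1] 661   $nTotal [1] 771   $percentSpecific [1] 86
```

Reading of the output: ~10% of the simulated transcriptome responds to the
microbiota in at least one compartment; 86% of those genes are significant
in exactly one of the four compartments — the fraction-specific share.
The same summary applied to published Venn counts works without any
expression data:

```r
specificitySummary(c(340, 894, 273, 444), total = 2256)
#> $nSpecific [1] 1951   $nTotal [1] 2256   $percentSpecific [1] 86
```

End-to-end drivers exist for both experiments:
`runGfVsCr(pipelineConfig(seed = 1), outDir = "out")` writes normalized
matrices, sample dendrograms (newick), per-compartment contrast tables,
the Venn partition (JSON), enrichment tables and a run manifest;
`runColonization()` adds the ANOVA gate, per-compartment consensus
clustering with chosen K, and per-cluster mean ± sd trajectories.  Both
are byte-reproducible under a fixed config and seed.

See the methods vignette
(`vignettes/site-specific-microbiota-response.Rmd`) for the models,
parameter defaults and their rationale, and known limitations.

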