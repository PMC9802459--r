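test_that("generation is deterministic and honors the null setting", {
  cfg <- synthConfig(nGenes = 30, nMale = 15, nFemale = 15,
                     sdvFraction = 0, seed = 9)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_false(any(studyTruth(a)$is_sdv))
  expect_true(all(studyTruth(a)$sdv_direction == "none"))
  expect_error(
    simulateStudy(synthConfig(nGenes = 5, nMale = 0, nFemale = 10)),
    "both sexes")
})

test_that("planted dispersion effects show up in group-wise sample variances", {
  st <- simulateStudy(synthConfig(
    nGenes = 150, nMale = 200, nFemale = 200, sdvFraction = 0.4,
    sdvLogSigmaEffect = 1.5, seed = 21))
  counts <- SummarizedExperiment::assay(st, "counts")
  truth <- studyTruth(st)
  male <- sampleSex(st) == "male"
  planted <- which(truth$is_sdv)
  # compare dispersion on the log scale to strip the mean component
  agree <- vapply(planted, function(g) {
    lv <- log1p(counts[g, ])
    d <- var(lv[male]) - var(lv[!male])
    (d > 0) == (truth$sdv_direction[g] == "male_higher")
  }, TRUE)
  expect_gt(mean(agree), 0.8)
  # and the moment-estimated overdispersion ordering agrees almost always
  momSigma <- function(y) (var(y) - mean(y)) / mean(y)^2
  agreeSigma <- vapply(planted, function(g) {
    d <- momSigma(counts[g, male]) - momSigma(counts[g, !male])
    (d > 0) == (truth$sdv_direction[g] == "male_higher")
  }, TRUE)
  expect_gte(mean(agreeSigma), 0.95)
})

test_that("null-gene counts have negative binomial moments", {
  # one gene, many samples, no covariate effects: Var ~ mu + sigma*mu^2
  cfg <- synthConfig(nGenes = 3, nMale = 5000, nFemale = 5000,
                     baselineLogMuRange = log(c(500, 500)),
                     baselineSigmaRange = c(0.1, 0.1),
                     sdvFraction = 0, covariateEffectScale = 0,
                     librarySizeRange = c(1e6, 1e6), seed = 5)
  st <- simulateStudy(cfg)
  counts <- SummarizedExperiment::assay(st, "counts")
  for (g in 1:3) {
    m <- mean(counts[g, ]); v <- var(counts[g, ])
    expect_equal(m, 500, tolerance = 0.05)
    expect_equal(v, m + 0.1 * m^2, tolerance = 0.15)
  }
})

test_that("planted outlier samples are caught by the PCA outlier rule", {
  cfg <- synthConfig(nGenes = 50, nMale = 30, nFemale = 30,
                     outlierFraction = 0.05, outlierScale = 3, seed = 13)
  st <- simulateStudy(cfg)
  out <- SummarizedExperiment::colData(st)$is_outlier
  expect_gt(sum(out), 0)
  cpm <- computeCPM(SummarizedExperiment::assay(st, "counts"))
  kept <- pcaOutlierSamples(log2(cpm + 1))
  expect_true(all(colnames(st)[out] %in% attr(kept, "removed")))
})

test_that("gene-set generator plants the requested label overlap", {
  universe <- sprintf("g%03d", 1:500)
  labels <- setNames(rep("not_sdv", 500), universe)
  labels[1:50] <- "male_higher"  # 10% label frequency
  sets <- simulateGeneSets(20, universe, labels, "male_higher",
                           plantedOverlap = 1, nPlanted = 10,
                           setSizeRange = c(30, 30), seed = 2)
  planted <- attr(sets, "planted")
  fracIn <- vapply(sets, function(s) mean(s %in% universe[1:50]), 0)
  # planted sets: all members labeled -> ~10x the 10% base frequency
  expect_true(all(fracIn[planted] == 1))
  # null sets: membership independent of labels
  expect_lt(mean(fracIn[!planted]), 0.3)
  expect_error(simulateGeneSets(5, character(0), labels, "male_higher"),
               "empty")
  expect_error(simulateGeneSets(5, universe, labels, "male_higher",
                                plantedOverlap = 1.4), "plantedOverlap")
})

test_that("eGene labels carry the planted depletion", {
  genes <- sprintf("g%05d", 1:50000)
  sdv <- setNames(rep(c(TRUE, FALSE), c(10000, 40000)), genes)
  lab <- simulateEGeneLabels(list(t1 = sdv), depletionFactor = 0.5,
                             baseRate = 0.4, seed = 3)[[1]]
  expect_equal(mean(lab[sdv]), 0.2, tolerance = 0.05)
  expect_equal(mean(lab[!sdv]), 0.4, tolerance = 0.03)
  # degenerate factors
  none <- simulateEGeneLabels(list(t1 = sdv), 0, baseRate = 0.4,
                              seed = 4)[[1]]
  expect_false(any(none[sdv]))
  indep <- simulateEGeneLabels(list(t1 = sdv), 1, baseRate = 0.4,
                               seed = 5)[[1]]
  expect_equal(mean(indep[sdv]), mean(indep[!sdv]), tolerance = 0.04)
})

test_that("single-cell generator gives exclusive markers and is reproducible", {
  sc <- simulateSCCounts(nCellsPerType = c(20, 15, 10), seed = 8)
  sc2 <- simulateSCCounts(nCellsPerType = c(20, 15, 10), seed = 8)
  expect_identical(sc$counts, sc2$counts)
  marker <- sc$counts["marker_type1_01", ]
  expect_true(all(marker[sc$cellType != "type1"] == 0))
  hk <- sc$counts["hk_001", ]
  expect_gt(mean(hk > 0), 0.9)
})
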