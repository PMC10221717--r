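test_that("double-positive titer formula matches its printed form", {
  mk <- function(dp, actinOnly, n = 20000) {
    TwoChannelCounts(nPosAOnly = actinOnly, nPosBOnly = 0, nDoublePos = dp,
                     nDoubleNeg = n - actinOnly - dp)
  }
  # no double positives -> titer 0
  expect_identical(
    titerValue(titerFromDoublePositives(mk(0, 1000), 2e6, 1, 0.1)), 0)

  # (dp 100, actin+ 1000) x 2e6 cells / 0.1 mL -> 2e6 iu/mL
  res <- titerFromDoublePositives(mk(100, 900), 2e6, 1, 0.1)
  expect_equal(titerValue(res), 2e6)
  expect_identical(titerMethod(res), "double_positive")
  expect_equal(intermediates(res)$infectedFraction, 0.1)

  # no beta-actin positives: cells undetected
  noCells <- TwoChannelCounts(nPosAOnly = 0, nPosBOnly = 5, nDoublePos = 0,
                              nDoubleNeg = 19995)
  expect_error(titerFromDoublePositives(noCells, 2e6, 1, 0.1),
               class = "dropletTiterEstimationError")
})

test_that("linkage titer formula divides by the actin concentration", {
  expect_identical(titerValue(titerFromLinkage(0, 500, 1e6, 1, 1)), 0)
  # linkage equal to the reference: every cell infected
  expect_equal(titerValue(titerFromLinkage(500, 500, 1e6, 1, 1)), 1e6)
  expect_error(titerFromLinkage(10, 0, 1e6, 1, 1),
               class = "dropletTiterEstimationError")

  # DuplexResult method agrees with the numeric method
  counts <- TwoChannelCounts(nPosAOnly = 7000, nPosBOnly = 100,
                             nDoublePos = 700, nDoubleNeg = 12200)
  dup <- duplexAnalysis(counts)
  a <- titerFromLinkage(dup, nCellsTotal = 2e6, dilution = 1,
                        inoculumVolumeMl = 0.1)
  b <- titerFromLinkage(linkageValue(dup), copiesPerUl(dup@concA),
                        2e6, 1, 0.1)
  expect_equal(titerValue(a), titerValue(b))
  expect_identical(titerMethod(a), "linkage")
})

test_that("clean simulation recovers the reference titer via linkage", {
  truth <- 1.73e7
  cfg <- smallCfg()
  cellCfg <- cleanCellCfg(moi = 0.074, trueTiter = truth,
                          occupancyModel = "empirical")
  est <- vapply(1:8, function(s) {
    batch <- simulateCellAssay(cellCfg, cfg, seed = 700 + s)
    dup <- suppressWarnings(duplexAnalysis(countBatch(batch),
                                           cfg@dropletVolumeNl))
    titerValue(titerFromLinkage(dup, cellCfg@nCellsTotal,
                                cellCfg@dilutionFactor,
                                cellCfg@inoculumVolumeMl))
  }, numeric(1))
  expect_equal(mean(est), truth, tolerance = 0.15)
})

test_that("free viral RNA drives the double-positive estimator upward", {
  truth <- 1.73e7
  cfg <- smallCfg()
  cellCfg <- CellAssayConfig(
    moi = 0.074, freeActinRnaRate = 1, freeViralRnaRate = 15,
    inoculumVolumeMl = inoculumVolumeForMoi(0.074, truth, 1, 2e6))
  eq1 <- eq2 <- numeric(6)
  for (s in 1:6) {
    batch <- simulateCellAssay(cellCfg, cfg, seed = 800 + s)
    cc <- countBatch(batch)
    dup <- suppressWarnings(duplexAnalysis(cc, cfg@dropletVolumeNl))
    eq1[s] <- titerValue(titerFromDoublePositives(
      cc, 2e6, 1, cellCfg@inoculumVolumeMl))
    eq2[s] <- titerValue(titerFromLinkage(dup, 2e6, 1,
                                          cellCfg@inoculumVolumeMl))
  }
  # direct double-positive counting overestimates; linkage stays closer
  expect_true(all(eq1 > eq2))
  expect_gt(mean(eq1), truth)
  expect_lt(abs(mean(eq2) - truth), abs(mean(eq1) - truth))
})

test_that("titers scale coherently with dilution and inoculum volume", {
  counts <- TwoChannelCounts(nPosAOnly = 7000, nPosBOnly = 100,
                             nDoublePos = 700, nDoubleNeg = 12200)
  dup <- duplexAnalysis(counts)
  t1 <- titerValue(titerFromDoublePositives(counts, 2e6, 1, 0.1))
  t2 <- titerValue(titerFromLinkage(dup, 2e6, 1, 0.1))
  expect_equal(titerValue(titerFromDoublePositives(counts, 2e6, 2, 0.1)),
               2 * t1)
  expect_equal(titerValue(titerFromLinkage(dup, 2e6, 2, 0.1)), 2 * t2)
  expect_equal(titerValue(titerFromDoublePositives(counts, 2e6, 1, 0.2)),
               t1 / 2)
  expect_equal(titerValue(titerFromLinkage(dup, 2e6, 1, 0.2)), t2 / 2)
})

test_that("MOI bookkeeping round-trips through the titer", {
  expect_identical(moiFromTiter(0, 0.2, 1, 2e6), 0)
  expect_equal(moiFromTiter(1.1e8, 0.2, 1, 2e6), 11)
  v <- inoculumVolumeForMoi(0.4, 1.73e7, 1, 2e6)
  expect_equal(moiFromTiter(1.73e7, v, 1, 2e6), 0.4)
  expect_error(moiFromTiter(1e6, 0.1, 1, 0),
               class = "dropletTiterDomainError")
})

test_that("infected-fraction conversion supports the Poisson correction", {
  expect_identical(infectedFractionToIu(0, 1e6), 0)
  expect_identical(infectedFractionToIu(0, 1e6, poissonCorrect = TRUE), 0)
  expect_equal(infectedFractionToIu(0.0713, 1e6, poissonCorrect = TRUE),
               7.40e4, tolerance = 0.005)
  expect_error(infectedFractionToIu(1, 1e6, poissonCorrect = TRUE),
               class = "dropletTiterDomainError")
  # small-fraction limit: corrected/uncorrected -> 1
  f <- 1e-4
  expect_equal(infectedFractionToIu(f, 1e6, poissonCorrect = TRUE) /
                 infectedFractionToIu(f, 1e6), 1, tolerance = 1e-3)
})

test_that("linkage-based infected fraction converges to 1 - exp(-MOI)", {
  cfg <- AssayConfig(nDroplets = 200000L, reactionVolumeUl = 200)
  cellCfg <- cleanCellCfg(moi = 0.4, nCellsLoaded = 20000)
  batch <- simulateCellAssay(cellCfg, cfg, seed = 909)
  dup <- suppressWarnings(duplexAnalysis(countBatch(batch),
                                         cfg@dropletVolumeNl))
  frac <- titerFromLinkage(dup, cellCfg@nCellsTotal, 1,
                           cellCfg@inoculumVolumeMl)
  expect_equal(intermediates(frac)$infectedFraction, 1 - exp(-0.4),
               tolerance = 0.03)
})

test_that("proportional cell-lysis scaling barely shifts the linkage titer", {
  # the working assumption of the assay: degradation affects infected and
  # uninfected cells alike, so the infected:uninfected relationship --
  # and with it the linkage titer -- moves little when both free-RNA
  # rates scale together (modest-contamination regime)
  truth <- 1.73e7
  cfg <- smallCfg()
  meanTiter <- function(actinRate, viralRate) {
    cellCfg <- CellAssayConfig(
      moi = 0.4, freeActinRnaRate = actinRate, freeViralRnaRate = viralRate,
      inoculumVolumeMl = inoculumVolumeForMoi(0.4, truth, 1, 2e6))
    mean(vapply(1:5, function(s) {
      batch <- simulateCellAssay(cellCfg, cfg, seed = 1000 + s)
      dup <- suppressWarnings(duplexAnalysis(countBatch(batch),
                                             cfg@dropletVolumeNl))
      titerValue(titerFromLinkage(dup, 2e6, 1, cellCfg@inoculumVolumeMl))
    }, numeric(1)))
  }
  base <- meanTiter(0.05, 0.5)
  scaled <- meanTiter(0.10, 1.0)
  expect_lt(abs(scaled / base - 1), 0.10)
})
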