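test_that("Poisson partitioning matches closed-form occupancy probabilities", {
  cfg <- smallCfg()
  # empty reaction
  expect_true(all(withr::with_seed(1,
    sampleCopiesPerDroplet(0, cfg)) == 0L))
  expect_error(sampleCopiesPerDroplet(-1, cfg),
               class = "dropletTiterDomainError")

  # lambda = 0.5: fraction of zero-copy droplets ~ exp(-0.5), 3-sd binomial
  lam <- 0.5
  conc <- lam / (cfg@dropletVolumeNl / 1000)
  copies <- withr::with_seed(42, sampleCopiesPerDroplet(conc, cfg))
  p0 <- exp(-lam)
  tol <- 3 * sqrt(p0 * (1 - p0) / cfg@nDroplets)
  expect_lt(abs(mean(copies == 0) - p0), tol)

  # lambda = 5: essentially all droplets positive
  conc5 <- 5 / (cfg@dropletVolumeNl / 1000)
  copies5 <- withr::with_seed(43, sampleCopiesPerDroplet(conc5, cfg))
  expect_gte(mean(copies5 > 0), 0.99)
})

test_that("partitioning conserves total copies within Poisson noise", {
  cfg <- smallCfg()
  for (lam in c(0.1, 0.5, 2)) {
    conc <- lam / (cfg@dropletVolumeNl / 1000)
    total <- sum(withr::with_seed(100 + lam * 10,
                                  sampleCopiesPerDroplet(conc, cfg)))
    expected <- lam * cfg@nDroplets
    expect_lt(abs(total - expected), 3 * sqrt(expected))
  }
})

test_that("duplex virus simulation encapsulates targets independently", {
  cfg <- smallCfg()
  mkPrep <- function(label, lam, ratio = 1) {
    conc <- lam / (cfg@dropletVolumeNl / 1000)                # copies/uL
    titer <- conc * cfg@reactionVolumeUl * 1000 *
      cfg@dilutionFactor / (cfg@sampleVolumeUl * ratio)       # iu/mL
    VirusPrep(label, titer, ratio)
  }

  # both titers zero -> all double-negative
  z <- simulateVirusAssay(list(VirusPrep("FAM", 0), VirusPrep("HEX", 0)),
                          cfg, seed = 1)
  expect_equal(nDoubleNegative(countBatch(z)), cfg@nDroplets)

  # duplicate channels rejected
  expect_error(
    simulateVirusAssay(list(mkPrep("FAM", 1), mkPrep("FAM", 1)), cfg, 1),
    class = "dropletTiterConfigError")

  # single prep at lambda = 1: positive fraction ~ 1 - exp(-1)
  b1 <- simulateVirusAssay(mkPrep("FAM", 1), cfg, seed = 5)
  p1 <- 1 - exp(-1)
  expect_lt(abs(nPositiveA(countBatch(b1)) / cfg@nDroplets - p1),
            3 * sqrt(p1 * (1 - p1) / cfg@nDroplets))

  # equal lambdas 0.1: double-positive fraction ~ (1 - exp(-0.1))^2
  b2 <- simulateVirusAssay(list(mkPrep("FAM", 0.1), mkPrep("HEX", 0.1)),
                           cfg, seed = 6)
  pdp <- (1 - exp(-0.1))^2
  expect_lt(abs(nDoublePositive(countBatch(b2)) / cfg@nDroplets - pdp),
            3 * sqrt(pdp * (1 - pdp) / cfg@nDroplets))

  # independence at assorted lambda pairs, 99% binomial bounds
  z99 <- qnorm(0.995)
  for (lams in list(c(0.3, 0.3), c(1, 0.2), c(0.05, 1.5))) {
    b <- simulateVirusAssay(list(mkPrep("FAM", lams[1]),
                                 mkPrep("HEX", lams[2])),
                            cfg, seed = sum(lams * 100))
    pdp <- (1 - exp(-lams[1])) * (1 - exp(-lams[2]))
    obs <- nDoublePositive(countBatch(b)) / cfg@nDroplets
    expect_lt(abs(obs - pdp),
              z99 * sqrt(pdp * (1 - pdp) / cfg@nDroplets))
  }
})

test_that("simulation is deterministic given config and seed", {
  cfg <- smallCfg(5000L)
  prep <- VirusPrep("FAM", 2e5, 20.16)
  b1 <- simulateVirusAssay(prep, cfg, seed = 99)
  b2 <- simulateVirusAssay(prep, cfg, seed = 99)
  expect_identical(as.data.frame(dropletData(b1)),
                   as.data.frame(dropletData(b2)))
  expect_identical(batchProvenance(b1)$seed, 99)

  # byte-identical exported event tables
  model <- AmplitudeModel()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeEventTable(renderAmplitudes(b1, model), f1)
  writeEventTable(renderAmplitudes(b2, model), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("cell occupancy follows the configured model", {
  cfg <- smallCfg()
  # Poisson loading: empty fraction ~ exp(-0.1) for 2000 cells / 20000
  ccP <- cleanCellCfg(moi = 0, nCellsLoaded = 2000)
  occ <- withr::with_seed(7, sampleCellOccupancy(ccP, cfg))
  p0 <- exp(-0.1)
  expect_lt(abs(mean(occ == 0) - p0),
            3 * sqrt(p0 * (1 - p0) / cfg@nDroplets))
  expect_lt(abs(mean(occ) - 0.1), 3 * sqrt(0.1 / cfg@nDroplets))

  # no cells loaded -> all empty
  cc0 <- cleanCellCfg(moi = 0, nCellsLoaded = 0)
  expect_true(all(sampleCellOccupancy(cc0, cfg) == 0L))

  # empirical model reproduces the category probabilities (99% bounds)
  ccE <- CellAssayConfig(moi = 0, occupancyModel = "empirical")
  occE <- withr::with_seed(8, sampleCellOccupancy(ccE, cfg))
  z99 <- qnorm(0.995)
  probs <- ccE@occupancyProbs
  for (k in seq_along(probs)) {
    obs <- mean(occE == k - 1L)
    expect_lt(abs(obs - probs[k]),
              z99 * sqrt(probs[k] * (1 - probs[k]) / cfg@nDroplets))
  }

  # invalid occupancy vector rejected at construction
  expect_error(CellAssayConfig(occupancyProbs = numeric(0)))
})

test_that("Poisson infection model hits the 1 - exp(-MOI) fraction", {
  expect_false(any(withr::with_seed(1, infectCells(1e4, 0))))
  expect_error(infectCells(10, -1), class = "dropletTiterDomainError")

  frHigh <- mean(withr::with_seed(2, infectCells(1e5, 11)))
  expect_gte(frHigh, 0.9999 - 3 * sqrt(1e-4 / 1e5) - 1e-4)
  expect_gte(frHigh, 0.999)

  p <- 1 - exp(-0.074)   # ~ 0.0713
  fr <- mean(withr::with_seed(3, infectCells(2e5, 0.074)))
  expect_lt(abs(fr - p), 3 * sqrt(p * (1 - p) / 2e5))
})

test_that("cell assay channel states follow the positivity rules", {
  cfg <- smallCfg()
  # no infection, no free RNA -> channel B silent
  b0 <- simulateCellAssay(cleanCellCfg(moi = 0), cfg, seed = 1)
  expect_equal(nPositiveB(countBatch(b0)), 0)

  # without free viral RNA, B+ droplets are exactly infected-cell droplets
  b1 <- simulateCellAssay(cleanCellCfg(moi = 0.5), cfg, seed = 2)
  df <- dropletData(b1)
  expect_equal(sum(df$chBPositive), sum(df$infectedCells >= 1L))
  expect_identical(df$chAPositive, df$cells >= 1L)

  # beta-actin debris at 9 copies/cell makes apparent actin copies ~ 10x
  # the encapsulated cell count
  ccDebris <- CellAssayConfig(moi = 0, occupancyModel = "poisson",
                              nCellsLoaded = 2000, freeActinRnaRate = 9,
                              freeViralRnaRate = 0)
  b2 <- simulateCellAssay(ccDebris, cfg, seed = 3)
  df2 <- dropletData(b2)
  nCells <- sum(df2$cells)
  totalActin <- nCells + sum(df2$freeActinCopies)
  expect_lt(abs(totalActin / nCells - 10), 0.5)
})

test_that("amplitude rendering round-trips through midpoint thresholds", {
  cfg <- smallCfg(5000L)
  prep <- VirusPrep("FAM", 3e5, 20.16)
  batch <- simulateVirusAssay(prep, cfg, seed = 21)
  model <- AmplitudeModel(rainFraction = 0)   # >> 6 sd separation

  events <- renderAmplitudes(batch, model, seed = 22)
  counts <- classifyEvents(events, midpointThresholds(model))
  expect_identical(nPositiveA(counts), nPositiveA(countBatch(batch)))
  expect_identical(nPositiveB(counts), nPositiveB(countBatch(batch)))

  # all-negative batch stays inside the negative cluster
  bNeg <- simulateVirusAssay(VirusPrep("FAM", 0), cfg, seed = 23)
  eNeg <- renderAmplitudes(bNeg, model, seed = 24)
  expect_true(all(eNeg$ch1_amplitude < midpointThresholds(model)[["ch1"]]))

  # rain fraction ~ 5% of positives fall between the clusters
  modelRain <- AmplitudeModel(rainFraction = 0.05)
  eRain <- renderAmplitudes(batch, modelRain, seed = 25)
  pos <- dropletData(batch)$chAPositive
  lo <- modelRain@negativeMean[1] + 4 * modelRain@clusterSd[1]
  hi <- modelRain@positiveMean[1] - 4 * modelRain@clusterSd[1]
  rained <- eRain$ch1_amplitude[pos] > lo & eRain$ch1_amplitude[pos] < hi
  nPos <- sum(pos)
  expect_lt(abs(mean(rained) - 0.05 * (hi - lo) /
                  (modelRain@positiveMean[1] - modelRain@negativeMean[1])),
            3 * sqrt(0.05 * 0.95 / nPos) + 0.01)
})
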