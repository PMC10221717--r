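# Shared fixtures: configs are built in code, no stored data.

smallCfg <- function(n = 20000L, ...) AssayConfig(nDroplets = n, ...)

# Exact-probability quadrant table of the three-species Poisson model
# (free A, free B, linked AB). Non-integer "counts" are intentional: they
# let closed-form identities be checked to machine precision.
exactThreeSpeciesCounts <- function(lambdaA, lambdaB, lambdaL, n = 1e6) {
  pAneg <- exp(-(lambdaA + lambdaL))
  pBneg <- exp(-(lambdaB + lambdaL))
  pBothNeg <- exp(-(lambdaA + lambdaB + lambdaL))
  TwoChannelCounts(
    nPosAOnly = n * (pBneg - pBothNeg),
    nPosBOnly = n * (pAneg - pBothNeg),
    nDoublePos = n * (1 - pAneg - pBneg + pBothNeg),
    nDoubleNeg = n * pBothNeg
  )
}

# Simulate quadrant counts of two independent Poisson targets directly at
# the count level (fast path for calibration loops).
simulateIndependentCounts <- function(lambdaA, lambdaB, n = 20000L) {
  pA <- 1 - exp(-lambdaA)
  pB <- 1 - exp(-lambdaB)
  probs <- c(pA * (1 - pB), (1 - pA) * pB, pA * pB, (1 - pA) * (1 - pB))
  draw <- stats::rmultinom(1, n, probs)[, 1]
  TwoChannelCounts(nPosAOnly = draw[1], nPosBOnly = draw[2],
                   nDoublePos = draw[3], nDoubleNeg = draw[4])
}

# A cell-assay config with Poisson occupancy and no contamination: the
# regime where the estimators are consistent for 1 - exp(-MOI).
cleanCellCfg <- function(moi, trueTiter = 1.73e7, nCellsTotal = 2e6,
                         nCellsLoaded = 2000, dilution = 1,
                         occupancyModel = "poisson", ...) {
  CellAssayConfig(
    nCellsTotal = nCellsTotal, nCellsLoaded = nCellsLoaded, moi = moi,
    occupancyModel = occupancyModel,
    freeActinRnaRate = 0, freeViralRnaRate = 0,
    inoculumVolumeMl = if (moi > 0)
      inoculumVolumeForMoi(moi, trueTiter, dilution, nCellsTotal)
    else 0.1,
    dilutionFactor = dilution, ...)
}
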