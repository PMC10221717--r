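#' @include AllClasses.R duplex-linkage.R
NULL

#' Infectious titer from direct double-positive counting
#'
#' The infected-cell fraction is taken as the double-positive droplet count
#' divided by the beta-actin-positive droplet count (A-only plus double
#' positive), then scaled to a titer:
#' \deqn{Titer = \frac{(actin^+ viral^+)}{actin^+} \times
#'       \frac{N_{cells} \times Dilution}{V}}
#' No correction is applied for random co-encapsulation of free viral RNA
#' with uninfected cells -- that confounder is exactly what makes this
#' estimator overshoot, and quantifying the overshoot is the point of
#' offering both methods.
#'
#' @param counts a \code{\link{TwoChannelCounts}} with channel A = beta-actin
#'   (cell marker), channel B = viral target.
#' @param nCellsTotal total number of cells used for infection.
#' @param dilution dilution of the virus suspension used for infection.
#' @param inoculumVolumeMl volume of virus suspension used for infection
#'   (mL), > 0.
#' @return a \code{\link{TiterResult}} with method \code{"double_positive"}.
#' @examples
#' counts <- TwoChannelCounts(nPosAOnly = 900, nPosBOnly = 0,
#'                            nDoublePos = 100, nDoubleNeg = 19000)
#' titerValue(titerFromDoublePositives(counts, nCellsTotal = 2e6,
#'                                     dilution = 1,
#'                                     inoculumVolumeMl = 0.1))
#' @export
titerFromDoublePositives <- function(counts, nCellsTotal, dilution,
                                     inoculumVolumeMl) {
  if (inoculumVolumeMl <= 0) stopConfig("inoculum volume must be > 0")
  nActinPos <- nPositiveA(counts)
  if (nActinPos < 1)
    stopEstimation("no beta-actin-positive droplets: no cells detected")
  frac <- counts@nDoublePos / nActinPos
  titer <- frac * nCellsTotal * dilution / inoculumVolumeMl
  new("TiterResult", titerIuPerMl = titer, method = "double_positive",
      intermediates = list(
        infectedFraction = frac,
        nDoublePos = counts@nDoublePos,
        nActinPos = nActinPos,
        nCellsTotal = nCellsTotal,
        dilution = dilution,
        inoculumVolumeMl = inoculumVolumeMl))
}

#' @describeIn titerFromLinkage titer from an explicit linkage value and
#'   beta-actin concentration (both in copies/uL; their quotient is the
#'   infected-cell fraction):
#'   \deqn{Titer = \frac{Linkage}{c_{actin}} \times
#'         \frac{N_{cells} \times Dilution}{V}}
#' @param cActinCopiesPerUl beta-actin reference concentration (copies/uL),
#'   > 0.
#' @param nCellsTotal total number of cells used for infection.
#' @param dilution dilution of the virus suspension used for infection.
#' @param inoculumVolumeMl volume of virus suspension used for infection
#'   (mL), > 0.
#' @examples
#' titerValue(titerFromLinkage(50, cActinCopiesPerUl = 500,
#'                             nCellsTotal = 2e6, dilution = 1,
#'                             inoculumVolumeMl = 0.1))
#' @export
setMethod("titerFromLinkage", "numeric",
  function(x, cActinCopiesPerUl, nCellsTotal, dilution, inoculumVolumeMl) {
    if (inoculumVolumeMl <= 0) stopConfig("inoculum volume must be > 0")
    if (!is.finite(cActinCopiesPerUl) || cActinCopiesPerUl <= 0)
      stopEstimation("beta-actin concentration must be > 0")
    if (x < 0) stopDomain("linkage must be >= 0")
    frac <- x / cActinCopiesPerUl
    titer <- frac * nCellsTotal * dilution / inoculumVolumeMl
    new("TiterResult", titerIuPerMl = titer, method = "linkage",
        intermediates = list(
          infectedFraction = frac,
          linkageCopiesPerUl = x,
          cActinCopiesPerUl = cActinCopiesPerUl,
          nCellsTotal = nCellsTotal,
          dilution = dilution,
          inoculumVolumeMl = inoculumVolumeMl))
  })

#' @describeIn titerFromLinkage titer from a \code{\link{DuplexResult}}
#'   whose channel A is the beta-actin reference; uses its linkage value and
#'   marginal A concentration.
#' @export
setMethod("titerFromLinkage", "DuplexResult",
  function(x, nCellsTotal, dilution, inoculumVolumeMl) {
    titerFromLinkage(linkageValue(x),
                     cActinCopiesPerUl = copiesPerUl(x@concA),
                     nCellsTotal = nCellsTotal, dilution = dilution,
                     inoculumVolumeMl = inoculumVolumeMl)
  })

#' Multiplicity of infection implied by a titer
#'
#' \code{moi = titer x volume / (dilution x nCellsTotal)}: infectious units
#' delivered per cell.
#'
#' @param titerIuPerMl infectious titer (iu/mL).
#' @param inoculumVolumeMl inoculum volume (mL).
#' @param dilution dilution factor of the suspension.
#' @param nCellsTotal number of cells infected, >= 1.
#' @return the MOI.
#' @export
moiFromTiter <- function(titerIuPerMl, inoculumVolumeMl, dilution,
                         nCellsTotal) {
  if (nCellsTotal < 1) stopDomain("nCellsTotal must be >= 1")
  titerIuPerMl * inoculumVolumeMl / (dilution * nCellsTotal)
}

#' Inoculum volume needed to hit a target MOI
#'
#' Inverse of \code{\link{moiFromTiter}}; used by the scenario builders to
#' keep (titer, MOI, volume, dilution, cell count) mutually consistent.
#'
#' @inheritParams moiFromTiter
#' @param moi target multiplicity of infection, > 0.
#' @return the inoculum volume in mL.
#' @export
inoculumVolumeForMoi <- function(moi, titerIuPerMl, dilution, nCellsTotal) {
  if (titerIuPerMl <= 0) stopDomain("titer must be > 0")
  moi * dilution * nCellsTotal / titerIuPerMl
}

#' Infectious units from an infected-cell fraction
#'
#' Uncorrected: \code{iu = fraction x nCellsTotal} (an infected cell counts
#' as one infectious unit, the convention of the droplet-based estimators).
#' With \code{poissonCorrect = TRUE} the fraction is first mapped through
#' \code{-ln(1 - fraction)} to account for multiply-infected cells; the two
#' agree as the fraction tends to 0.
#'
#' @param fraction infected-cell fraction in [0, 1) (strictly < 1 when
#'   correcting).
#' @param nCellsTotal number of cells.
#' @param poissonCorrect logical, default \code{FALSE}.
#' @return infectious units.
#' @export
infectedFractionToIu <- function(fraction, nCellsTotal,
                                 poissonCorrect = FALSE) {
  if (fraction < 0) stopDomain("fraction must be >= 0")
  if (poissonCorrect) {
    if (fraction >= 1)
      stopDomain("fraction must be < 1 for the Poisson correction")
    return(nCellsTotal * (-log(1 - fraction)))
  }
  if (fraction > 1) stopDomain("fraction must be <= 1")
  nCellsTotal * fraction
}
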