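#' @include AllClasses.R quant-core.R
NULL

#' Marginal concentrations of two targets from quadrant counts
#'
#' Each target's channel-positive count (single-positive plus
#' double-positive) is fed to the single-channel Poisson estimator
#' independently; random co-encapsulation does not bias the marginals.
#'
#' @param counts a \code{\link{TwoChannelCounts}}.
#' @param dropletVolumeNl droplet volume in nanolitres.
#' @param confLevel nominal confidence level.
#' @return list with \code{ConcentrationEstimate}s \code{A} and \code{B}.
#' @export
duplexConcentrations <- function(counts, dropletVolumeNl = 0.85,
                                 confLevel = 0.95) {
  list(
    A = estimateConcentration(counts@nTotal, nPositiveA(counts),
                              dropletVolumeNl, confLevel),
    B = estimateConcentration(counts@nTotal, nPositiveB(counts),
                              dropletVolumeNl, confLevel)
  )
}

#' Double positives expected under independent co-encapsulation
#'
#' @param counts a \code{\link{TwoChannelCounts}}.
#' @return \code{nTotal x (fraction A-positive) x (fraction B-positive)}.
#' @export
expectedDoublePositives <- function(counts) {
  counts@nTotal * (nPositiveA(counts) / counts@nTotal) *
    (nPositiveB(counts) / counts@nTotal)
}

#' Linked-species mean occupancy (signed) from quadrant counts
#'
#' Under a three-species Poisson model -- free target A, free target B, and
#' a linked species carrying both, with mean occupancies
#' \code{lambda_a}, \code{lambda_b}, \code{lambda_L} -- the quadrant
#' negative fractions give \code{lambda_A = lambda_a + lambda_L},
#' \code{lambda_B = lambda_b + lambda_L} and
#' \code{lambda_union = lambda_a + lambda_b + lambda_L}, so
#' \code{lambda_L = lambda_A + lambda_B - lambda_union}. This is the signed
#' plug-in MLE; sampling noise makes it negative about half the time when no
#' linked species exists.
#'
#' @param counts a \code{\link{TwoChannelCounts}}; requires at least one
#'   double-negative droplet and unsaturated marginals.
#' @return the signed linked-occupancy estimate (copies per droplet).
#' @export
linkageLambda <- function(counts) {
  n <- counts@nTotal
  if (counts@nDoubleNeg < 1)
    stopSaturation("no double-negative droplets: union channel saturated")
  lambdaA <- estimateLambda(n, nPositiveA(counts))$lambda
  lambdaB <- estimateLambda(n, nPositiveB(counts))$lambda
  lambdaUnion <- -log(counts@nDoubleNeg / n)
  lambdaA + lambdaB - lambdaUnion
}

#' Linkage: concentration of linked entities (excess double positives)
#'
#' The number of double positives over and beyond those predicted by random
#' co-encapsulation, expressed as a concentration. Computed as
#' \code{max(linkageLambda(counts), 0) / (dropletVolumeNl / 1000)} -- the
#' negative tail of the null sampling distribution is clipped to 0 for
#' reporting (retrieve the raw value with \code{\link{linkageLambda}} or
#' from a \code{\link{DuplexResult}}).
#'
#' @inheritParams duplexConcentrations
#' @return linkage in copies/uL, >= 0.
#' @export
linkage <- function(counts, dropletVolumeNl = 0.85) {
  raw <- linkageLambda(counts)
  concentrationFromLambda(max(raw, 0), dropletVolumeNl)
}

#' Full duplex analysis of one well
#'
#' Marginal concentrations, expected vs observed double positives, and the
#' linkage statistic in one \code{\link{DuplexResult}}. A warning is raised
#' when any quadrant holds fewer than 10 droplets: with near-empty
#' quadrants (poor cluster separation or extreme occupancy) the linkage
#' estimate is unstable, though it is still reported.
#'
#' @inheritParams duplexConcentrations
#' @return a \code{\link{DuplexResult}}.
#' @examples
#' counts <- TwoChannelCounts(nPosAOnly = 4000, nPosBOnly = 300,
#'                            nDoublePos = 250, nDoubleNeg = 15450)
#' duplexAnalysis(counts)
#' @export
duplexAnalysis <- function(counts, dropletVolumeNl = 0.85,
                           confLevel = 0.95) {
  quadrants <- c(counts@nPosAOnly, counts@nPosBOnly, counts@nDoublePos,
                 counts@nDoubleNeg)
  if (any(quadrants < 10))
    warning("quadrant with < 10 droplets: linkage estimate may be unstable",
            call. = FALSE)
  marg <- duplexConcentrations(counts, dropletVolumeNl, confLevel)
  raw <- linkageLambda(counts)
  new("DuplexResult",
      concA = marg$A, concB = marg$B,
      expectedDoublePos = expectedDoublePositives(counts),
      observedDoublePos = counts@nDoublePos,
      linkageCopiesPerUl = concentrationFromLambda(max(raw, 0),
                                                   dropletVolumeNl),
      lambdaLinked = raw,
      dropletVolumeNl = dropletVolumeNl)
}

#' Fraction of reference entities carrying the linked target
#'
#' Divides the linkage concentration by a reference concentration (the
#' beta-actin cell marker in the infected-cell assay), yielding the
#' infected-cell fraction. Values above 1 are possible when the model is
#' violated and are flagged with a warning: free RNA cannot inflate the
#' linkage numerator, but it does inflate a marker-based denominator, so
#' quotients > 1 indicate an unusual reference.
#'
#' @param linkageCopiesPerUl linkage concentration, >= 0.
#' @param cReferenceCopiesPerUl reference concentration, > 0.
#' @return the quotient.
#' @export
linkedFraction <- function(linkageCopiesPerUl, cReferenceCopiesPerUl) {
  if (!is.finite(cReferenceCopiesPerUl) || cReferenceCopiesPerUl <= 0)
    stopDomain("reference concentration must be > 0")
  if (linkageCopiesPerUl < 0) stopDomain("linkage must be >= 0")
  frac <- linkageCopiesPerUl / cReferenceCopiesPerUl
  if (frac > 1)
    warning("linked fraction > 1: reference concentration lower than ",
            "linkage; check the reference channel", call. = FALSE)
  frac
}
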