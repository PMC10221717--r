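#' @include AllClasses.R conditions.R
NULL

## Wilson score interval on a binomial proportion. Chosen over the normal
## approximation for its behaviour at fractions near 0 and 1, where digital
## PCR wells routinely operate.
wilsonInterval <- function(x, n, confLevel = 0.95) {
  z <- stats::qnorm(1 - (1 - confLevel) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # algebraically the bound is exactly 1 (0) at p = 1 (0); pin it so the
  # -ln transform cannot pick up floating-point residue
  c(low = if (p == 0) 0 else max(0, centre - half),
    high = if (p == 1) 1 else min(1, centre + half))
}

#' Estimate mean copies per droplet from positive/negative counts
#'
#' The Poisson maximum-likelihood estimate from the negative fraction:
#' \code{lambda = -ln((nTotal - nPositive) / nTotal)}. The confidence
#' interval is a Wilson score interval on the negative fraction mapped
#' through \code{-ln} (the map is monotone decreasing, so the bounds swap).
#'
#' An all-positive well is saturated -- lambda is not estimable -- and
#' raises a typed saturation error rather than returning infinity. An
#' all-negative well returns \code{lambda = 0} with a one-sided interval.
#'
#' @param counts a \code{\link{ChannelCounts}}, or the total droplet count
#'   if \code{nPositive} is given.
#' @param nPositive positive droplet count when \code{counts} is numeric.
#' @param confLevel nominal confidence level (default 0.95).
#' @return list with \code{lambda}, \code{ciLow}, \code{ciHigh},
#'   \code{confLevel}, \code{nTotal}, \code{nPositive}.
#' @examples
#' estimateLambda(20000, 12642)$lambda   # ~ 1
#' @export
estimateLambda <- function(counts, nPositive = NULL, confLevel = 0.95) {
  if (is(counts, "ChannelCounts")) {
    nTot <- counts@nTotal; nPos <- counts@nPositive
  } else {
    if (is.null(nPositive))
      stopInput("supply a ChannelCounts or (nTotal, nPositive)")
    nTot <- as.numeric(counts); nPos <- as.numeric(nPositive)
  }
  if (nTot < 1) stopInput("nTotal must be >= 1")
  if (nPos < 0 || nPos > nTot)
    stopInput("nPositive must be in [0, nTotal]")
  if (nPos == nTot)
    stopSaturation(
      "all droplets positive: concentration not estimable (saturated well)")
  negFrac <- (nTot - nPos) / nTot
  lambda <- -log(negFrac)
  ci <- wilsonInterval(nTot - nPos, nTot, confLevel)
  list(
    lambda = lambda,
    ciLow = max(0, -log(ci[["high"]])),  # high negative fraction -> low lambda
    ciHigh = -log(ci[["low"]]),
    confLevel = confLevel,
    nTotal = nTot,
    nPositive = nPos
  )
}

#' Convert mean copies per droplet to a reaction concentration
#'
#' @param lambda mean copies per droplet, >= 0.
#' @param dropletVolumeNl droplet volume in nanolitres.
#' @return copies per uL of reaction: \code{lambda / (dropletVolumeNl/1000)}.
#' @export
concentrationFromLambda <- function(lambda, dropletVolumeNl) {
  if (!all(is.finite(dropletVolumeNl)) || any(dropletVolumeNl <= 0))
    stopConfig("dropletVolumeNl must be > 0")
  if (any(lambda < 0)) stopDomain("lambda must be >= 0")
  lambda / (dropletVolumeNl / 1000)
}

#' Estimate a target concentration in the reaction from droplet counts
#'
#' Combines \code{\link{estimateLambda}} and
#' \code{\link{concentrationFromLambda}} into a
#' \code{\link{ConcentrationEstimate}}.
#'
#' @inheritParams estimateLambda
#' @param dropletVolumeNl droplet volume in nanolitres (default 0.85).
#' @return a \code{\link{ConcentrationEstimate}}.
#' @export
estimateConcentration <- function(counts, nPositive = NULL,
                                  dropletVolumeNl = 0.85,
                                  confLevel = 0.95) {
  est <- estimateLambda(counts, nPositive, confLevel)
  new("ConcentrationEstimate",
      lambdaMean = est$lambda,
      copiesPerUl = concentrationFromLambda(est$lambda, dropletVolumeNl),
      ciLow = concentrationFromLambda(est$ciLow, dropletVolumeNl),
      ciHigh = concentrationFromLambda(est$ciHigh, dropletVolumeNl),
      confLevel = confLevel, nTotal = est$nTotal, nPositive = est$nPositive)
}

#' Classify an amplitude event table into quadrant counts
#'
#' A droplet is positive in a channel iff its amplitude strictly exceeds the
#' channel threshold; this replaces the droplet reader's thresholding step.
#'
#' @param events data.frame with columns \code{ch1_amplitude} and
#'   \code{ch2_amplitude} (the simulator's event-table export).
#' @param thresholds numeric of length 2 (or named \code{ch1}, \code{ch2}).
#' @return a \code{\link{TwoChannelCounts}}.
#' @export
classifyEvents <- function(events, thresholds) {
  if (is.null(events) || nrow(events) == 0L)
    stopInput("event table is empty")
  if (!all(c("ch1_amplitude", "ch2_amplitude") %in% names(events)))
    stopInput("event table needs ch1_amplitude and ch2_amplitude columns")
  if (length(thresholds) != 2L || any(!is.finite(thresholds)))
    stopInput("supply two finite thresholds")
  if (!is.null(names(thresholds)) && all(c("ch1", "ch2") %in%
                                         names(thresholds)))
    thresholds <- thresholds[c("ch1", "ch2")]
  a <- events$ch1_amplitude > thresholds[[1]]
  b <- events$ch2_amplitude > thresholds[[2]]
  TwoChannelCounts(
    nPosAOnly = sum(a & !b), nPosBOnly = sum(!a & b),
    nDoublePos = sum(a & b), nDoubleNeg = sum(!a & !b)
  )
}

#' Back-calculate the genome titer of the original sample
#'
#' Scales a reaction concentration to copies per mL of the undiluted
#' sample: \code{conc x (reactionVolume / sampleVolume) x dilution x 1000}.
#'
#' @param conc a \code{\link{ConcentrationEstimate}} or numeric copies/uL of
#'   reaction.
#' @param cfg an \code{\link{AssayConfig}} providing the volumes and
#'   dilution.
#' @return a \code{\link{SampleTiter}}.
#' @examples
#' cfg <- AssayConfig(sampleVolumeUl = 2)
#' copiesPerMl(sampleTiter(100, cfg))   # 1e6
#' @export
sampleTiter <- function(conc, cfg) {
  if (cfg@sampleVolumeUl <= 0) stopConfig("sample volume must be > 0")
  scale <- (cfg@reactionVolumeUl / cfg@sampleVolumeUl) *
    cfg@dilutionFactor * 1000
  if (is(conc, "ConcentrationEstimate")) {
    value <- conc@copiesPerUl
    deriv <- list(copiesPerUl = value, ciLowPerMl = conc@ciLow * scale,
                  ciHighPerMl = conc@ciHigh * scale)
  } else {
    if (!is.finite(conc) || conc < 0) stopDomain("concentration must be >= 0")
    value <- conc
    deriv <- list(copiesPerUl = value)
  }
  new("SampleTiter", copiesPerMlSample = value * scale,
      derivation = c(deriv, list(
        reactionVolumeUl = cfg@reactionVolumeUl,
        sampleVolumeUl = cfg@sampleVolumeUl,
        dilutionFactor = cfg@dilutionFactor)))
}

#' Ratio of genome titer to infectious titer
#'
#' The quotient genome copies per infectious unit -- a preparation-specific
#' constant reflecting damaged particles and non-encapsidated RNA.
#'
#' @param genomeTiter genome titer (vp/mL) or a \code{\link{SampleTiter}}.
#' @param infectiousTiter infectious titer (iu/mL), > 0.
#' @param genomeCi optional length-2 CI on the genome titer; propagated by
#'   scaling.
#' @return the ratio, with attribute \code{ci} when \code{genomeCi} given.
#' @export
genomeToInfectiousRatio <- function(genomeTiter, infectiousTiter,
                                    genomeCi = NULL) {
  if (is(genomeTiter, "SampleTiter")) genomeTiter <- copiesPerMl(genomeTiter)
  if (!is.finite(infectiousTiter) || infectiousTiter <= 0)
    stopDomain("infectious titer must be > 0")
  ratio <- genomeTiter / infectiousTiter
  if (!is.null(genomeCi)) {
    stopifnot(length(genomeCi) == 2L)
    attr(ratio, "ci") <- sort(genomeCi / infectiousTiter)
  }
  ratio
}
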