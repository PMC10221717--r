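#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Assay-level configuration for one ddPCR reaction well
#'
#' Describes the physical partitioning of a reaction: how many droplets are
#' generated, their volume, the total reaction volume, and how much sample
#' (virus or cell suspension) went into the mix at which dilution. All
#' concentration arithmetic in the package routes through these values, in
#' particular through \code{dropletVolumeNl}, the single constant converting
#' mean copies per droplet (lambda) to copies/uL.
#'
#' @slot nDroplets integer, droplets generated for the well (~20,000 on the
#'   instrument class emulated here).
#' @slot dropletVolumeNl numeric, droplet volume in nanolitres (default 0.85).
#' @slot reactionVolumeUl numeric, total reaction volume in microlitres.
#' @slot sampleVolumeUl numeric, volume of virus/cell suspension added.
#' @slot dilutionFactor numeric >= 1, pre-dilution of the sample.
#' @slot rngSeed integer, default seed used by simulation calls on this config.
#'
#' @examples
#' cfg <- AssayConfig(nDroplets = 20000L)
#' cfg
#' @export
setClass("AssayConfig",
  representation(
    nDroplets = "integer",
    dropletVolumeNl = "numeric",
    reactionVolumeUl = "numeric",
    sampleVolumeUl = "numeric",
    dilutionFactor = "numeric",
    rngSeed = "integer"
  )
)

setValidity("AssayConfig", function(object) {
  msg <- character()
  if (length(object@nDroplets) != 1L || is.na(object@nDroplets) ||
      object@nDroplets < 1L)
    msg <- c(msg, "nDroplets must be a single integer >= 1")
  vols <- c(object@dropletVolumeNl, object@reactionVolumeUl,
            object@sampleVolumeUl)
  if (any(!is.finite(vols)) || any(vols <= 0))
    msg <- c(msg, "all volumes must be finite and > 0")
  if (!is.finite(object@dilutionFactor) || object@dilutionFactor < 1)
    msg <- c(msg, "dilutionFactor must be >= 1")
  # the emulsion cannot hold more liquid than the reaction provides
  if (length(msg) == 0L &&
      object@nDroplets * object@dropletVolumeNl >
      object@reactionVolumeUl * 1000)
    msg <- c(msg, "nDroplets * dropletVolumeNl exceeds the reaction volume")
  if (length(msg)) msg else TRUE
})

#' @rdname AssayConfig-class
#' @param nDroplets,dropletVolumeNl,reactionVolumeUl,sampleVolumeUl,dilutionFactor,rngSeed
#'   see the corresponding slots.
#' @return An \code{AssayConfig} object.
#' @export
AssayConfig <- function(nDroplets = 20000L, dropletVolumeNl = 0.85,
                        reactionVolumeUl = 20, sampleVolumeUl = 2,
                        dilutionFactor = 1, rngSeed = 1L) {
  new("AssayConfig", nDroplets = as.integer(nDroplets),
      dropletVolumeNl = as.numeric(dropletVolumeNl),
      reactionVolumeUl = as.numeric(reactionVolumeUl),
      sampleVolumeUl = as.numeric(sampleVolumeUl),
      dilutionFactor = as.numeric(dilutionFactor),
      rngSeed = as.integer(rngSeed))
}

#' A virus preparation entering a duplex or single-target assay
#'
#' The preparation is parameterised by its infectious titer and the ratio of
#' total genome copies to infectious units; damaged particles and
#' non-encapsidated genomes make this ratio > 1 and preparation-specific.
#' \code{freeRnaFraction} adds further naked RNA as a fraction of the genome
#' copies, on top of whatever the ratio already accounts for.
#'
#' @slot label character, fluorescence channel of the probe set, "FAM"
#'   (channel A/1) or "HEX" (channel B/2).
#' @slot infectiousTiterIuPerMl numeric >= 0, infectious units per mL.
#' @slot genomePerInfectiousRatio numeric >= 1, genome copies per infectious
#'   unit.
#' @slot freeRnaFraction numeric >= 0, extra non-encapsidated RNA copies as a
#'   fraction of genome copies (default 0: the ratio is taken as already
#'   calibrated against ddPCR).
#' @export
setClass("VirusPrep",
  representation(
    label = "character",
    infectiousTiterIuPerMl = "numeric",
    genomePerInfectiousRatio = "numeric",
    freeRnaFraction = "numeric"
  )
)

setValidity("VirusPrep", function(object) {
  msg <- character()
  if (!object@label %in% c("FAM", "HEX"))
    msg <- c(msg, "label must be 'FAM' or 'HEX'")
  if (!is.finite(object@infectiousTiterIuPerMl) ||
      object@infectiousTiterIuPerMl < 0)
    msg <- c(msg, "infectiousTiterIuPerMl must be >= 0")
  if (!is.finite(object@genomePerInfectiousRatio) ||
      object@genomePerInfectiousRatio < 1)
    msg <- c(msg, "genomePerInfectiousRatio must be >= 1")
  if (!is.finite(object@freeRnaFraction) || object@freeRnaFraction < 0)
    msg <- c(msg, "freeRnaFraction must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname VirusPrep-class
#' @param label,infectiousTiterIuPerMl,genomePerInfectiousRatio,freeRnaFraction
#'   see the corresponding slots.
#' @return A \code{VirusPrep} object.
#' @export
VirusPrep <- function(label = "FAM", infectiousTiterIuPerMl,
                      genomePerInfectiousRatio = 1,
                      freeRnaFraction = 0) {
  new("VirusPrep", label = label,
      infectiousTiterIuPerMl = as.numeric(infectiousTiterIuPerMl),
      genomePerInfectiousRatio = as.numeric(genomePerInfectiousRatio),
      freeRnaFraction = as.numeric(freeRnaFraction))
}

#' Configuration of a single-cell infection assay
#'
#' Holds everything the infected-cell titer estimators need: the infection
#' bookkeeping (total cells infected, dilution, inoculum volume, MOI), the
#' droplet cell-occupancy model, and the free-floating RNA contamination
#' rates that confound the double-positive count.
#'
#' @slot nCellsTotal numeric, total number of cells used for infection
#'   (N_cells in the titer formulas).
#' @slot nCellsLoaded numeric, cells added to the ddPCR reaction (1000-2000
#'   is typical); drives the Poisson occupancy model and, through the
#'   realised encapsulated-cell count, the free-RNA totals.
#' @slot moi numeric >= 0, multiplicity of infection.
#' @slot occupancyModel character, "empirical" (draws cells-per-droplet from
#'   \code{occupancyProbs}) or "poisson" (mean \code{nCellsLoaded/nDroplets}).
#' @slot occupancyProbs numeric probability vector over 0,1,2,... cells per
#'   droplet; default is the microscopy-measured distribution
#'   (60.4/28.3/8.5/2.8 percent for 0-3 cells).
#' @slot freeActinRnaRate numeric >= 0, expected free beta-actin RNA copies
#'   per encapsulated cell (lysis debris).
#' @slot freeViralRnaRate numeric >= 0, expected free viral RNA copies per
#'   encapsulated infected cell.
#' @slot inoculumVolumeMl numeric > 0, volume of virus suspension used for
#'   infection (V in the titer formulas).
#' @slot dilutionFactor numeric >= 1, dilution of the virus suspension used
#'   for infection.
#' @export
setClass("CellAssayConfig",
  representation(
    nCellsTotal = "numeric",
    nCellsLoaded = "numeric",
    moi = "numeric",
    occupancyModel = "character",
    occupancyProbs = "numeric",
    freeActinRnaRate = "numeric",
    freeViralRnaRate = "numeric",
    inoculumVolumeMl = "numeric",
    dilutionFactor = "numeric"
  )
)

#' Default empirical cells-per-droplet distribution (0, 1, 2, 3 cells)
#' measured by fluorescence microscopy of stained-cell emulsions.
#' @export
empiricalOccupancyProbs <- c(0.604, 0.283, 0.085, 0.028)

setValidity("CellAssayConfig", function(object) {
  msg <- character()
  if (object@nCellsTotal < 1)
    msg <- c(msg, "nCellsTotal must be >= 1")
  if (object@nCellsLoaded < 0 || object@nCellsLoaded > object@nCellsTotal)
    msg <- c(msg, "nCellsLoaded must be in [0, nCellsTotal]")
  if (!is.finite(object@moi) || object@moi < 0)
    msg <- c(msg, "moi must be >= 0")
  if (!object@occupancyModel %in% c("empirical", "poisson"))
    msg <- c(msg, "occupancyModel must be 'empirical' or 'poisson'")
  if (object@occupancyModel == "empirical") {
    p <- object@occupancyProbs
    if (length(p) < 1L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "occupancyProbs must be non-negative and sum to 1 (1e-9)")
  }
  if (object@freeActinRnaRate < 0 || object@freeViralRnaRate < 0)
    msg <- c(msg, "free RNA rates must be >= 0")
  if (!is.finite(object@inoculumVolumeMl) || object@inoculumVolumeMl <= 0)
    msg <- c(msg, "inoculumVolumeMl must be > 0")
  if (object@dilutionFactor < 1)
    msg <- c(msg, "dilutionFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname CellAssayConfig-class
#' @param nCellsTotal,nCellsLoaded,moi,occupancyModel,occupancyProbs,freeActinRnaRate,freeViralRnaRate,inoculumVolumeMl,dilutionFactor
#'   see the corresponding slots.
#' @return A \code{CellAssayConfig} object.
#' @export
CellAssayConfig <- function(nCellsTotal = 2e6, nCellsLoaded = 2000,
                            moi = 0.074,
                            occupancyModel = c("empirical", "poisson"),
                            occupancyProbs = empiricalOccupancyProbs,
                            freeActinRnaRate = 1, freeViralRnaRate = 15,
                            inoculumVolumeMl = 0.1, dilutionFactor = 1) {
  occupancyModel <- match.arg(occupancyModel)
  # renormalise to absorb rounding in published percentages
  occupancyProbs <- occupancyProbs / sum(occupancyProbs)
  new("CellAssayConfig", nCellsTotal = as.numeric(nCellsTotal),
      nCellsLoaded = as.numeric(nCellsLoaded), moi = as.numeric(moi),
      occupancyModel = occupancyModel,
      occupancyProbs = as.numeric(occupancyProbs),
      freeActinRnaRate = as.numeric(freeActinRnaRate),
      freeViralRnaRate = as.numeric(freeViralRnaRate),
      inoculumVolumeMl = as.numeric(inoculumVolumeMl),
      dilutionFactor = as.numeric(dilutionFactor))
}

#' Two-channel Gaussian cluster model for rendering droplet amplitudes
#'
#' Positive and negative droplets draw fluorescence from well-separated
#' Gaussian clusters; a configurable fraction of positives falls uniformly
#' between the cluster means ("rain").
#'
#' @slot negativeMean,positiveMean numeric(2), cluster means per channel
#'   (a.u.), channel 1 then channel 2.
#' @slot clusterSd numeric(2), within-cluster standard deviation per channel.
#' @slot rainFraction numeric in [0, 1), fraction of positive droplets that
#'   rain between the clusters.
#' @export
setClass("AmplitudeModel",
  representation(
    negativeMean = "numeric",
    positiveMean = "numeric",
    clusterSd = "numeric",
    rainFraction = "numeric"
  )
)

setValidity("AmplitudeModel", function(object) {
  msg <- character()
  if (length(object@negativeMean) != 2L || length(object@positiveMean) != 2L ||
      length(object@clusterSd) != 2L)
    msg <- c(msg, "negativeMean, positiveMean and clusterSd must have length 2")
  else {
    if (any(object@positiveMean <= object@negativeMean))
      msg <- c(msg, "positiveMean must exceed negativeMean in each channel")
    if (any(object@clusterSd <= 0))
      msg <- c(msg, "clusterSd must be > 0")
  }
  if (object@rainFraction < 0 || object@rainFraction >= 1)
    msg <- c(msg, "rainFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname AmplitudeModel-class
#' @param negativeMean,positiveMean,clusterSd,rainFraction see the
#'   corresponding slots.
#' @return An \code{AmplitudeModel} object.
#' @export
AmplitudeModel <- function(negativeMean = c(1000, 1000),
                           positiveMean = c(9000, 7000),
                           clusterSd = c(250, 250),
                           rainFraction = 0) {
  new("AmplitudeModel", negativeMean = as.numeric(negativeMean),
      positiveMean = as.numeric(positiveMean),
      clusterSd = as.numeric(clusterSd),
      rainFraction = as.numeric(rainFraction))
}

#' Simulated droplet batch for one reaction well
#'
#' Couples the per-droplet latent contents (genome copies, cells, infected
#' cells, free RNA copies, depending on the assay type) with the observed
#' boolean channel states, plus the generating configuration and seed so a
#' batch can be regenerated exactly.
#'
#' @slot droplets a \code{\link[S4Vectors]{DataFrame}} with one row per
#'   droplet; always contains logical columns \code{chAPositive} and
#'   \code{chBPositive}.
#' @slot config the generating \code{AssayConfig}.
#' @slot provenance list with at least \code{type} ("virus" or "cell") and
#'   \code{seed}.
#' @export
setClass("DropletBatch",
  representation(
    droplets = "DataFrame",
    config = "AssayConfig",
    provenance = "list"
  )
)

setValidity("DropletBatch", function(object) {
  msg <- character()
  df <- object@droplets
  if (nrow(df) != object@config@nDroplets)
    msg <- c(msg, "droplet count must equal config nDroplets")
  for (col in c("chAPositive", "chBPositive")) {
    if (!col %in% colnames(df) || !is.logical(df[[col]]))
      msg <- c(msg, sprintf("droplets must contain a logical '%s' column", col))
  }
  if (!all(c("type", "seed") %in% names(object@provenance)))
    msg <- c(msg, "provenance must record 'type' and 'seed'")
  if (length(msg)) msg else TRUE
})

#' Positive/negative droplet counts for a single channel
#'
#' @slot nTotal total accepted droplets (>= 1).
#' @slot nPositive droplets positive in the channel, 0 <= nPositive <= nTotal.
#' @export
setClass("ChannelCounts",
  representation(nTotal = "numeric", nPositive = "numeric"))

setValidity("ChannelCounts", function(object) {
  msg <- character()
  if (object@nTotal < 1) msg <- c(msg, "nTotal must be >= 1")
  if (object@nPositive < 0 || object@nPositive > object@nTotal)
    msg <- c(msg, "nPositive must be in [0, nTotal]")
  if (length(msg)) msg else TRUE
})

#' @rdname ChannelCounts-class
#' @param nTotal,nPositive see the corresponding slots.
#' @return A \code{ChannelCounts} object.
#' @export
ChannelCounts <- function(nTotal, nPositive) {
  new("ChannelCounts", nTotal = as.numeric(nTotal),
      nPositive = as.numeric(nPositive))
}

#' Four-quadrant droplet counts for a duplex assay
#'
#' The 2x2 table of droplet counts by joint channel state -- the sufficient
#' statistic for all duplex estimation in this package. Counts are stored as
#' numerics so that exact-probability (non-integer) tables can be analysed.
#'
#' @slot nTotal total droplets.
#' @slot nPosAOnly positive in channel A (FAM) only.
#' @slot nPosBOnly positive in channel B (HEX) only.
#' @slot nDoublePos positive in both channels.
#' @slot nDoubleNeg negative in both channels.
#' @export
setClass("TwoChannelCounts",
  representation(
    nTotal = "numeric",
    nPosAOnly = "numeric",
    nPosBOnly = "numeric",
    nDoublePos = "numeric",
    nDoubleNeg = "numeric"
  )
)

setValidity("TwoChannelCounts", function(object) {
  msg <- character()
  q <- c(object@nPosAOnly, object@nPosBOnly, object@nDoublePos,
         object@nDoubleNeg)
  if (any(q < 0)) msg <- c(msg, "all quadrant counts must be >= 0")
  if (object@nTotal < 1) msg <- c(msg, "nTotal must be >= 1")
  if (abs(sum(q) - object@nTotal) > 1e-6 * max(1, object@nTotal))
    msg <- c(msg, "quadrant counts must sum to nTotal")
  if (length(msg)) msg else TRUE
})

#' @rdname TwoChannelCounts-class
#' @param nPosAOnly,nPosBOnly,nDoublePos,nDoubleNeg see the corresponding
#'   slots.
#' @param nTotal optional; defaults to the sum of the four quadrants.
#' @return A \code{TwoChannelCounts} object.
#' @export
TwoChannelCounts <- function(nPosAOnly, nPosBOnly, nDoublePos, nDoubleNeg,
                             nTotal = nPosAOnly + nPosBOnly + nDoublePos +
                               nDoubleNeg) {
  new("TwoChannelCounts", nTotal = as.numeric(nTotal),
      nPosAOnly = as.numeric(nPosAOnly), nPosBOnly = as.numeric(nPosBOnly),
      nDoublePos = as.numeric(nDoublePos),
      nDoubleNeg = as.numeric(nDoubleNeg))
}

#' Concentration estimate for one target in one well
#'
#' @slot lambdaMean estimated mean copies per droplet.
#' @slot copiesPerUl copies per microlitre of reaction.
#' @slot ciLow,ciHigh confidence bounds on copiesPerUl.
#' @slot confLevel the nominal confidence level.
#' @slot nTotal,nPositive the counts the estimate derives from.
#' @export
setClass("ConcentrationEstimate",
  representation(
    lambdaMean = "numeric",
    copiesPerUl = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    confLevel = "numeric",
    nTotal = "numeric",
    nPositive = "numeric"
  )
)

setValidity("ConcentrationEstimate", function(object) {
  msg <- character()
  if (object@lambdaMean < 0) msg <- c(msg, "lambdaMean must be >= 0")
  tol <- 1e-9 * max(1, abs(object@copiesPerUl))
  if (object@ciLow > object@copiesPerUl + tol ||
      object@copiesPerUl > object@ciHigh + tol)
    msg <- c(msg, "ciLow <= copiesPerUl <= ciHigh must hold")
  if (length(msg)) msg else TRUE
})

#' Genome titer of the original sample
#'
#' @slot copiesPerMlSample copies per mL of the undiluted sample (vp/mL under
#'   the one-genome-per-particle convention).
#' @slot derivation list of the inputs the back-calculation used
#'   (copies/uL, reaction and sample volumes, dilution, scaled CI).
#' @export
setClass("SampleTiter",
  representation(copiesPerMlSample = "numeric", derivation = "list"))

setValidity("SampleTiter", function(object) {
  if (object@copiesPerMlSample < 0) "copiesPerMlSample must be >= 0" else TRUE
})

#' Duplex analysis result: marginal concentrations and linkage
#'
#' @slot concA,concB marginal \code{ConcentrationEstimate}s per target.
#' @slot expectedDoublePos double-positive droplets expected under random
#'   co-encapsulation of independent targets.
#' @slot observedDoublePos observed double-positive droplets.
#' @slot linkageCopiesPerUl concentration of linked (co-packaged) entities;
#'   clipped at 0 for reporting.
#' @slot lambdaLinked the raw signed linked-occupancy estimate (copies per
#'   droplet), retained for calibration.
#' @slot dropletVolumeNl droplet volume used for the copies/uL conversion.
#' @export
setClass("DuplexResult",
  representation(
    concA = "ConcentrationEstimate",
    concB = "ConcentrationEstimate",
    expectedDoublePos = "numeric",
    observedDoublePos = "numeric",
    linkageCopiesPerUl = "numeric",
    lambdaLinked = "numeric",
    dropletVolumeNl = "numeric"
  )
)

setValidity("DuplexResult", function(object) {
  msg <- character()
  if (object@expectedDoublePos < 0)
    msg <- c(msg, "expectedDoublePos must be >= 0")
  if (object@linkageCopiesPerUl < 0)
    msg <- c(msg, "linkageCopiesPerUl must be >= 0 (raw value in lambdaLinked)")
  if (length(msg)) msg else TRUE
})

#' Infectious titer estimate
#'
#' @slot titerIuPerMl infectious units per mL.
#' @slot method "double_positive" (direct double-positive counting) or
#'   "linkage" (excess-double-positive based).
#' @slot intermediates list of every quantity entering the formula
#'   (infected fraction, double-positive or linkage value, beta-actin
#'   reference, N_cells, dilution, inoculum volume).
#' @export
setClass("TiterResult",
  representation(
    titerIuPerMl = "numeric",
    method = "character",
    intermediates = "list"
  )
)

setValidity("TiterResult", function(object) {
  msg <- character()
  if (object@titerIuPerMl < 0) msg <- c(msg, "titerIuPerMl must be >= 0")
  if (!object@method %in% c("double_positive", "linkage"))
    msg <- c(msg, "method must be 'double_positive' or 'linkage'")
  if (length(msg)) msg else TRUE
})

#' Specification of a simulated experiment scenario
#'
#' @slot scenario one of "single_virus_gradient", "duplex_mixture",
#'   "single_cell_titer".
#' @slot replicates number of replicate runs (>= 1).
#' @slot seeds integer vector, one seed per replicate.
#' @slot config scenario-specific configuration list (see the
#'   \code{*Spec()} constructors).
#' @export
setClass("ScenarioSpec",
  representation(
    scenario = "character",
    replicates = "integer",
    seeds = "integer",
    config = "list"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (!object@scenario %in% c("single_virus_gradient", "duplex_mixture",
                              "single_cell_titer"))
    msg <- c(msg, "unknown scenario")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(object@seeds) != object@replicates)
    msg <- c(msg, "need exactly one seed per replicate")
  if (length(msg)) msg else TRUE
})

#' Report from a scenario run
#'
#' @slot scenario the scenario name.
#' @slot estimates data.frame with one row per well (replicate x condition)
#'   of estimates and ground truth.
#' @slot summary data.frame of per-condition mean, SEM and relative bias
#'   (plus regression diagnostics for gradient scenarios).
#' @slot manifest list echoing the spec (scenario, seeds, configs, package
#'   version); a run is reproducible from the manifest alone.
#' @export
setClass("ScenarioReport",
  representation(
    scenario = "character",
    estimates = "data.frame",
    summary = "data.frame",
    manifest = "list"
  )
)
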