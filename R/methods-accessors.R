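#' @include AllGenerics.R
NULL

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
setMethod("nTotal", "ChannelCounts", function(x) x@nTotal)
#' @rdname accessors
setMethod("nPositive", "ChannelCounts", function(x) x@nPositive)

#' @rdname accessors
setMethod("nTotal", "TwoChannelCounts", function(x) x@nTotal)
#' @rdname accessors
setMethod("nPositiveA", "TwoChannelCounts",
          function(x) x@nPosAOnly + x@nDoublePos)
#' @rdname accessors
setMethod("nPositiveB", "TwoChannelCounts",
          function(x) x@nPosBOnly + x@nDoublePos)
#' @rdname accessors
setMethod("nDoublePositive", "TwoChannelCounts", function(x) x@nDoublePos)
#' @rdname accessors
setMethod("nDoubleNegative", "TwoChannelCounts", function(x) x@nDoubleNeg)

#' @rdname accessors
setMethod("lambdaMean", "ConcentrationEstimate", function(x) x@lambdaMean)
#' @rdname accessors
setMethod("copiesPerUl", "ConcentrationEstimate", function(x) x@copiesPerUl)
#' @rdname accessors
setMethod("ciLow", "ConcentrationEstimate", function(x) x@ciLow)
#' @rdname accessors
setMethod("ciHigh", "ConcentrationEstimate", function(x) x@ciHigh)
#' @rdname accessors
setMethod("nTotal", "ConcentrationEstimate", function(x) x@nTotal)
#' @rdname accessors
setMethod("nPositive", "ConcentrationEstimate", function(x) x@nPositive)

#' @rdname accessors
setMethod("copiesPerMl", "SampleTiter", function(x) x@copiesPerMlSample)

#' @rdname accessors
setMethod("linkageValue", "DuplexResult", function(x) x@linkageCopiesPerUl)
#' @rdname accessors
setMethod("lambdaLinked", "DuplexResult", function(x) x@lambdaLinked)
#' @rdname accessors
setMethod("nDoublePositive", "DuplexResult", function(x) x@observedDoublePos)

#' @rdname accessors
setMethod("titerValue", "TiterResult", function(x) x@titerIuPerMl)
#' @rdname accessors
setMethod("titerMethod", "TiterResult", function(x) x@method)
#' @rdname accessors
setMethod("intermediates", "TiterResult", function(x) x@intermediates)

#' @rdname accessors
setMethod("dropletData", "DropletBatch", function(x) x@droplets)
#' @rdname accessors
setMethod("assayConfig", "DropletBatch", function(x) x@config)
#' @rdname accessors
setMethod("batchProvenance", "DropletBatch", function(x) x@provenance)
#' @rdname accessors
setMethod("nTotal", "DropletBatch", function(x) nrow(x@droplets))

#' @rdname countBatch
setMethod("countBatch", "DropletBatch", function(x) {
  a <- x@droplets$chAPositive
  b <- x@droplets$chBPositive
  TwoChannelCounts(
    nPosAOnly = sum(a & !b),
    nPosBOnly = sum(!a & b),
    nDoublePos = sum(a & b),
    nDoubleNeg = sum(!a & !b)
  )
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "AssayConfig", function(object) {
  cat("AssayConfig:", object@nDroplets, "droplets x",
      object@dropletVolumeNl, "nL |", object@reactionVolumeUl,
      "uL reaction,", object@sampleVolumeUl, "uL sample, dilution",
      object@dilutionFactor, "\n")
})

setMethod("show", "VirusPrep", function(object) {
  cat(sprintf(
    "VirusPrep [%s]: %.3g iu/mL, %.4g genome copies/iu, free RNA x%.3g\n",
    object@label, object@infectiousTiterIuPerMl,
    object@genomePerInfectiousRatio, object@freeRnaFraction))
})

setMethod("show", "CellAssayConfig", function(object) {
  cat(sprintf(
    paste0("CellAssayConfig: %g cells infected (MOI %.3g), %g loaded, ",
           "occupancy '%s'\n  free RNA rates: actin %.3g/cell, ",
           "viral %.3g/infected cell; V = %g mL, dilution %g\n"),
    object@nCellsTotal, object@moi, object@nCellsLoaded,
    object@occupancyModel, object@freeActinRnaRate, object@freeViralRnaRate,
    object@inoculumVolumeMl, object@dilutionFactor))
})

setMethod("show", "DropletBatch", function(object) {
  cc <- countBatch(object)
  cat(sprintf(
    "DropletBatch (%s, seed %s): %d droplets | A+ %d, B+ %d, AB+ %d\n",
    object@provenance$type, object@provenance$seed, nrow(object@droplets),
    nPositiveA(cc), nPositiveB(cc), nDoublePositive(cc)))
})

setMethod("show", "TwoChannelCounts", function(object) {
  cat(sprintf(
    "TwoChannelCounts (n = %g): A-only %g | B-only %g | AB %g | neg %g\n",
    object@nTotal, object@nPosAOnly, object@nPosBOnly,
    object@nDoublePos, object@nDoubleNeg))
})

setMethod("show", "ConcentrationEstimate", function(object) {
  cat(sprintf(
    "ConcentrationEstimate: %.4g copies/uL (%.0f%% CI %.4g-%.4g), lambda %.4g [%g/%g positive]\n",
    object@copiesPerUl, 100 * object@confLevel, object@ciLow, object@ciHigh,
    object@lambdaMean, object@nPositive, object@nTotal))
})

setMethod("show", "SampleTiter", function(object) {
  cat(sprintf("SampleTiter: %.4g copies/mL of sample\n",
              object@copiesPerMlSample))
})

setMethod("show", "DuplexResult", function(object) {
  cat(sprintf(
    paste0("DuplexResult: A %.4g copies/uL, B %.4g copies/uL\n",
           "  double positives: %g observed vs %.1f expected under ",
           "independence\n  linkage: %.4g copies/uL (raw lambda %.4g)\n"),
    object@concA@copiesPerUl, object@concB@copiesPerUl,
    object@observedDoublePos, object@expectedDoublePos,
    object@linkageCopiesPerUl, object@lambdaLinked))
})

setMethod("show", "TiterResult", function(object) {
  cat(sprintf("TiterResult [%s]: %.4g iu/mL\n", object@method,
              object@titerIuPerMl))
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec '%s': %d replicate(s), seeds %s\n",
              object@scenario, object@replicates,
              paste(object@seeds, collapse = ", ")))
})

setMethod("show", "ScenarioReport", function(object) {
  cat(sprintf("ScenarioReport '%s': %d wells\n", object@scenario,
              nrow(object@estimates)))
  print(object@summary, digits = 4)
})
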