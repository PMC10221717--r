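#' @include AllClasses.R
NULL

#' Accessors for droplet-count and estimate classes
#'
#' Small accessor family mirroring the slot layout: total and per-channel
#' droplet counts, estimated lambda and concentration with its confidence
#' bounds, linkage values and titer results.
#'
#' @param x an object of the documented classes.
#' @return A numeric scalar (counts, lambda, concentrations, titers), a
#'   character scalar (\code{titerMethod}), a list (\code{intermediates}),
#'   or a \code{DataFrame} (\code{dropletData}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))
#' @rdname accessors
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))
#' @rdname accessors
#' @export
setGeneric("nPositiveA", function(x) standardGeneric("nPositiveA"))
#' @rdname accessors
#' @export
setGeneric("nPositiveB", function(x) standardGeneric("nPositiveB"))
#' @rdname accessors
#' @export
setGeneric("nDoublePositive", function(x) standardGeneric("nDoublePositive"))
#' @rdname accessors
#' @export
setGeneric("nDoubleNegative", function(x) standardGeneric("nDoubleNegative"))
#' @rdname accessors
#' @export
setGeneric("lambdaMean", function(x) standardGeneric("lambdaMean"))
#' @rdname accessors
#' @export
setGeneric("copiesPerUl", function(x) standardGeneric("copiesPerUl"))
#' @rdname accessors
#' @export
setGeneric("ciLow", function(x) standardGeneric("ciLow"))
#' @rdname accessors
#' @export
setGeneric("ciHigh", function(x) standardGeneric("ciHigh"))
#' @rdname accessors
#' @export
setGeneric("copiesPerMl", function(x) standardGeneric("copiesPerMl"))
#' @rdname accessors
#' @export
setGeneric("linkageValue", function(x) standardGeneric("linkageValue"))
#' @rdname accessors
#' @export
setGeneric("lambdaLinked", function(x) standardGeneric("lambdaLinked"))
#' @rdname accessors
#' @export
setGeneric("titerValue", function(x) standardGeneric("titerValue"))
#' @rdname accessors
#' @export
setGeneric("titerMethod", function(x) standardGeneric("titerMethod"))
#' @rdname accessors
#' @export
setGeneric("intermediates", function(x) standardGeneric("intermediates"))
#' @rdname accessors
#' @export
setGeneric("dropletData", function(x) standardGeneric("dropletData"))
#' @rdname accessors
#' @export
setGeneric("assayConfig", function(x) standardGeneric("assayConfig"))
#' @rdname accessors
#' @export
setGeneric("batchProvenance", function(x) standardGeneric("batchProvenance"))

#' Count droplets by channel state
#'
#' @param x a \code{DropletBatch} (or other object with channel states).
#' @return A \code{TwoChannelCounts} built from the object's observed
#'   channel states.
#' @export
setGeneric("countBatch", function(x) standardGeneric("countBatch"))

#' Infectious titer from linkage (excess double positives)
#'
#' @param x a \code{DuplexResult} (channel A = beta-actin reference) or the
#'   numeric linkage concentration in copies/uL.
#' @param ... passed to methods; see \code{\link{titerFromLinkage,numeric-method}}.
#' @return A \code{TiterResult} with method \code{"linkage"}.
#' @export
setGeneric("titerFromLinkage", function(x, ...) {
  standardGeneric("titerFromLinkage")
})

#' Summarise a scenario run as mean, SEM and bias per estimand
#'
#' @param x a \code{ScenarioReport} or the per-well estimates data.frame.
#' @param ... passed to methods.
#' @return A data.frame with one row per condition x estimand holding the
#'   replicate mean, SEM (over >= 2 replicates, else NA), ground truth and
#'   relative bias.
#' @export
setGeneric("summarizeReport", function(x, ...) {
  standardGeneric("summarizeReport")
})
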