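## Typed error conditions. Saturated / empty wells are real states a caller
## may want to branch on, so they carry condition classes instead of bare
## message strings, and downstream titer math never sees non-finite values.

stopSaturation <- function(msg) {
  stop(errorCondition(msg,
    class = c("dropletTiterSaturationError", "dropletTiterError")))
}

stopDomain <- function(msg) {
  stop(errorCondition(msg,
    class = c("dropletTiterDomainError", "dropletTiterError")))
}

stopConfig <- function(msg) {
  stop(errorCondition(msg,
    class = c("dropletTiterConfigError", "dropletTiterError")))
}

stopInput <- function(msg) {
  stop(errorCondition(msg,
    class = c("dropletTiterInputError", "dropletTiterError")))
}

stopEstimation <- function(msg) {
  stop(errorCondition(msg,
    class = c("dropletTiterEstimationError", "dropletTiterError")))
}
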