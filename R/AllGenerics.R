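#' @include AllClasses.R
NULL

#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @export
setGeneric("traceSignal", function(x) standardGeneric("traceSignal"))

#' @export
setGeneric("stepsApplied", function(x) standardGeneric("stepsApplied"))

#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @export
setGeneric("isRegular", function(x) standardGeneric("isRegular"))

#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @export
setGeneric("wellIds", function(x) standardGeneric("wellIds"))

#' @export
setGeneric("getTrace", function(x, well) standardGeneric("getTrace"))

#' @export
setGeneric("detrendMovingAverage", function(x, config = preprocessConfig())
  standardGeneric("detrendMovingAverage"))

#' @export
setGeneric("smoothMovingAverage", function(x, config = preprocessConfig())
  standardGeneric("smoothMovingAverage"))

#' @export
setGeneric("fitSinusoid", function(x, config = fitConfig())
  standardGeneric("fitSinusoid"))

#' @export
setGeneric("periodHours", function(x) standardGeneric("periodHours"))

#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @export
setGeneric("phaseHours", function(x) standardGeneric("phaseHours"))

#' @export
setGeneric("constantLevel", function(x) standardGeneric("constantLevel"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
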