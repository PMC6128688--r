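#' Accessor generics
#'
#' Small accessor generics used across the sweep, gating-model and
#' single-channel classes. They exist so user code never touches slots
#' directly.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The corresponding field; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("currentPA", function(x) standardGeneric("currentPA"))

#' @rdname accessors
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))

#' @rdname accessors
#' @export
setGeneric("vHoldMV", function(x) standardGeneric("vHoldMV"))

#' @rdname accessors
#' @export
setGeneric("stimOnsetMs", function(x) standardGeneric("stimOnsetMs"))

#' @rdname accessors
#' @export
setGeneric("stimDurationMs", function(x) standardGeneric("stimDurationMs"))

#' @rdname accessors
#' @export
setGeneric("stimAmplitude", function(x) standardGeneric("stimAmplitude"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("sweepId", function(x) standardGeneric("sweepId"))

#' @rdname accessors
#' @export
setGeneric("timesMs", function(x) standardGeneric("timesMs"))

#' @rdname accessors
#' @export
setGeneric("sweeps", function(x) standardGeneric("sweeps"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("stateNames", function(x) standardGeneric("stateNames"))

#' @rdname accessors
#' @export
setGeneric("stateCounts", function(x) standardGeneric("stateCounts"))

#' @rdname accessors
#' @export
setGeneric("gammaPS", function(x) standardGeneric("gammaPS"))

#' @rdname accessors
#' @export
setGeneric("eRevMV", function(x) standardGeneric("eRevMV"))

#' @rdname accessors
#' @export
setGeneric("levelMeans", function(x) standardGeneric("levelMeans"))

#' @rdname accessors
#' @export
setGeneric("levelSds", function(x) standardGeneric("levelSds"))

#' @rdname accessors
#' @export
setGeneric("levelWeights", function(x) standardGeneric("levelWeights"))

#' Whole-cell metric accessors
#'
#' Extract individual whole-cell mechanosensitive-current metrics from an
#' [MSCurrentMetrics] object produced by [analyzeSweep()].
#'
#' @param x an `MSCurrentMetrics` object.
#' @return A numeric scalar (`NA` where the metric is undefined).
#' @seealso [analyzeSweep()]
#' @name metric-accessors
NULL

#' @rdname metric-accessors
#' @export
setGeneric("baselinePA", function(x) standardGeneric("baselinePA"))

#' @rdname metric-accessors
#' @export
setGeneric("peakPA", function(x) standardGeneric("peakPA"))

#' @rdname metric-accessors
#' @export
setGeneric("slowPA", function(x) standardGeneric("slowPA"))

#' @rdname metric-accessors
#' @export
setGeneric("slowFraction", function(x) standardGeneric("slowFraction"))

#' @rdname metric-accessors
#' @export
setGeneric("fastComponent", function(x) standardGeneric("fastComponent"))
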