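#' @include AllClasses.R
NULL

#' @describeIn DoseResponsePanel-class dose-response measurement table.
#' @param object,x an object.
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @describeIn DoseResponsePanel-class drug metadata table (Cmax, risk).
#' @export
setGeneric("drugInfo", function(object) standardGeneric("drugInfo"))

#' @describeIn DoseResponsePanel-class drug identifiers in the panel.
#' @export
setGeneric("drugNames", function(object) standardGeneric("drugNames"))

#' Accessor generics for Hill samples, beat series and datasets
#'
#' \code{hillSamples} returns the bootstrap sample table;
#' \code{nBeats} the number of beats in a paced run; \code{apTrace} one
#' beat as an \linkS4class{APTrace}; \code{apTraces} the trace matrix
#' (samples x time points) of a dataset; \code{riskClass} the per-sample
#' risk factor.
#'
#' @param object,series,ds an object.
#' @param beat beat index.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("hillSamples", function(object) standardGeneric("hillSamples"))

#' @rdname accessors
#' @export
setGeneric("nBeats", function(object) standardGeneric("nBeats"))

#' @rdname accessors
#' @param ... passed to methods.
#' @export
setGeneric("apTrace", function(object, ...) standardGeneric("apTrace"))

#' @rdname accessors
#' @export
setGeneric("apTraces", function(object) standardGeneric("apTraces"))

#' @rdname accessors
#' @export
setGeneric("riskClass", function(object) standardGeneric("riskClass"))

#' @rdname accessors
#' @export
setGeneric("evalMetrics", function(object) standardGeneric("evalMetrics"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
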