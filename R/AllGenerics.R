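#' @rdname ReadSet
#' @param x a ReadSet (or other object with read accessors).
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' @rdname ReadSet
#' @export
setGeneric("readSeqs", function(x) standardGeneric("readSeqs"))

#' @rdname ReadSet
#' @export
setGeneric("isPerfect", function(x) standardGeneric("isPerfect"))

#' @rdname ReadSet
#' @export
setGeneric("isCorrected", function(x) standardGeneric("isCorrected"))

#' @rdname EvalCounts-class
#' @param x an EvalCounts object.
#' @export
setGeneric("evalCounts", function(x) standardGeneric("evalCounts"))
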