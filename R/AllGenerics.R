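#' @rdname ContrastScatteringSet-accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname ContrastScatteringSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ContrastScatteringSet-accessors
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))

#' @rdname ContrastScatteringSet-accessors
#' @export
setGeneric("contrastDeltas", function(x) standardGeneric("contrastDeltas"))

#' @rdname ContrastScatteringSet-accessors
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @rdname fitGPR
#' @export
setGeneric("fitGPR", function(data, spec, ...) standardGeneric("fitGPR"))

#' @rdname fitWLS
#' @export
setGeneric("fitWLS", function(data, ...) standardGeneric("fitWLS"))

#' @rdname logMarginalLikelihood
#' @export
setGeneric("logMarginalLikelihood",
  function(data, spec, ...) standardGeneric("logMarginalLikelihood"))

#' @rdname PartialEstimate-accessors
#' @export
setGeneric("estimateMeans", function(x) standardGeneric("estimateMeans"))

#' @rdname PartialEstimate-accessors
#' @export
setGeneric("errorBars", function(x) standardGeneric("errorBars"))

#' @rdname PartialEstimate-accessors
#' @export
setGeneric("posteriorCovariance",
  function(x) standardGeneric("posteriorCovariance"))

#' @rdname PartialEstimate-accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname gridSearch
#' @export
setGeneric("bestSpec", function(x) standardGeneric("bestSpec"))

#' @rdname gridSearch
#' @export
setGeneric("objectiveTable", function(x) standardGeneric("objectiveTable"))
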