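#' @include AllClasses.R
NULL

#' @rdname EHRCohort-accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("labEvents", function(x) standardGeneric("labEvents"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("codeEvents", function(x) standardGeneric("codeEvents"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("medEvents", function(x) standardGeneric("medEvents"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("demographics", function(x) standardGeneric("demographics"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("indexDays", function(x) standardGeneric("indexDays"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("recordSpans", function(x) standardGeneric("recordSpans"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("recordLabels", function(x) standardGeneric("recordLabels"))
#' @rdname EHRCohort-accessors
#' @export
setGeneric("recordLabels<-",
           function(x, value) standardGeneric("recordLabels<-"))

#' @rdname truncateAtIndex
#' @export
setGeneric("truncateAtIndex", function(x, ...)
  standardGeneric("truncateAtIndex"))

#' @rdname assignLabels
#' @export
setGeneric("assignLabels", function(x, malignancyCodes, window = c(4, 1095),
                                    ...)
  standardGeneric("assignLabels"))

#' @rdname cohortSummary
#' @export
setGeneric("cohortSummary", function(x, ...) standardGeneric("cohortSummary"))

#' @rdname curveValue
#' @export
setGeneric("curveValue", function(curve, day) standardGeneric("curveValue"))

#' @rdname SignatureModel-accessors
#' @export
setGeneric("mixing", function(object) standardGeneric("mixing"))
#' @rdname SignatureModel-accessors
#' @export
setGeneric("unmixing", function(object) standardGeneric("unmixing"))
#' @rdname SignatureModel-accessors
#' @export
setGeneric("nSources", function(object) standardGeneric("nSources"))
#' @rdname SignatureModel-accessors
#' @export
setGeneric("sourceAffine", function(object) standardGeneric("sourceAffine"))

#' @rdname inferExpressions
#' @export
setGeneric("inferExpressions", function(model, x, ...)
  standardGeneric("inferExpressions"))

#' @rdname shapleyValues
#' @export
setGeneric("shapleyValues",
  function(model, samples, background, nPermutations = 16L, seed = 1L, ...)
    standardGeneric("shapleyValues"))
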