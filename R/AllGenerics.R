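#' @name accessors
#' @title Accessors for timeArrow classes
#'
#' @description Slot accessors: `subjectId()`, `tsValues()` (the T x N
#' matrix), `subjectLabel()` (integer(0) when unlabeled), `subjects()`,
#' `nSubjects()`, `nTimepoints()`, `nComponents()`, `cohortLabels()`,
#' `modelParameters()`, `provenance()`, `attributions()`, `massVector()`.
#'
#' @param x an object of the documented classes.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))
#' @rdname accessors
#' @export
setGeneric("subjectLabel", function(x) standardGeneric("subjectLabel"))
#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("attributions", function(x) standardGeneric("attributions"))
#' @rdname accessors
#' @export
setGeneric("massVector", function(x) standardGeneric("massVector"))

#' @rdname accessors
setMethod("subjectId", "SubjectTimeSeries", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "SaliencyMap", function(x) x@subjectId)
#' @rdname accessors
setMethod("tsValues", "SubjectTimeSeries", function(x) x@values)
#' @rdname accessors
setMethod("subjectLabel", "SubjectTimeSeries", function(x) x@label)
#' @rdname accessors
setMethod("subjects", "Cohort", function(x) x@subjects)
#' @rdname accessors
setMethod("nSubjects", "Cohort", function(x) length(x@subjects))
#' @rdname accessors
setMethod("nTimepoints", "Cohort", function(x) x@nTimepoints)
#' @rdname accessors
setMethod("nComponents", "Cohort", function(x) x@nComponents)
#' @rdname accessors
setMethod("nTimepoints", "SubjectTimeSeries", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nComponents", "SubjectTimeSeries", function(x) ncol(x@values))

#' @rdname accessors
setMethod("cohortLabels", "Cohort", function(x) {
  vapply(x@subjects, function(s)
    if (length(s@label)) s@label else NA_integer_, integer(1))
})

#' @rdname accessors
setMethod("modelParameters", "TrainedModel", function(x) x@parameters)
#' @rdname accessors
setMethod("provenance", "TrainedModel", function(x) x@provenance)
#' @rdname accessors
setMethod("attributions", "SaliencyMap", function(x) x@attributions)
#' @rdname accessors
setMethod("massVector", "TimeDistribution", function(x) x@mass)

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries '%s': %d time points x %d components%s\n",
              object@subjectId, nrow(object@values), ncol(object@values),
              if (length(object@label))
                sprintf(", label = %d", object@label) else ""))
})

setMethod("show", "Cohort", function(object) {
  lab <- cohortLabels(object)
  cat(sprintf("Cohort '%s': %d subjects, %d time points x %d components\n",
              object@name, length(object@subjects), object@nTimepoints,
              object@nComponents))
  if (any(!is.na(lab)))
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE)))
})

setMethod("show", "TrainedModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("TrainedModel (%s): %s encoder %dx%d, attention %s, ",
                     "decoder %d, input size %d\n"),
              object@provenance, toupper(cfg@encoderKind), cfg@lstmLayers,
              cfg@lstmHidden,
              if (cfg@useAttention) sprintf("%d", cfg@attentionHidden)
              else "off", cfg@decoderHidden, cfg@inputSize))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap '%s' (%s%s): %d x %d\n", object@subjectId,
              object@direction, if (object@aligned) ", aligned" else "",
              nrow(object@attributions), ncol(object@attributions)))
})

setMethod("show", "TimeDistribution", function(object) {
  cat(sprintf("TimeDistribution over %d time points%s\n",
              length(object@mass),
              if (object@degenerate) " (degenerate)" else ""))
})
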