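#' @name dynFNC-accessors
#' @title Accessors for dynFNC objects
#' @description Accessor generics for the package's S4 containers; use
#'   these rather than reaching into slots.
#' @param x a dynFNC object.
NULL

#' @rdname dynFNC-accessors
#' @export
setGeneric("timecourses", function(x) standardGeneric("timecourses"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("realignment", function(x) standardGeneric("realignment"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("trueStatePath", function(x) standardGeneric("trueStatePath"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("meanDwell", function(x) standardGeneric("meanDwell"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("fractionTime", function(x) standardGeneric("fractionTime"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname dynFNC-accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

setMethod("timecourses", "SubjectTimecourses", function(x) x@data)
setMethod("realignment", "SubjectTimecourses", function(x) x@realignment)
setMethod("stage", "SubjectTimecourses", function(x) x@stage)
setMethod("trueStatePath", "SubjectTimecourses", function(x) x@trueStatePath)
setMethod("subjectID", "SubjectTimecourses", function(x) x@subject)
setMethod("groupLabel", "SubjectTimecourses", function(x) x@group)

setMethod("trajectory", "WindowedFNC", function(x) x@trajectory)
setMethod("windowStarts", "WindowedFNC", function(x) x@windowStarts)
setMethod("pairLabels", "WindowedFNC", function(x) x@pairNames)
setMethod("subjectID", "WindowedFNC", function(x) x@subject)
setMethod("groupLabel", "WindowedFNC", function(x) x@group)

setMethod("centroids", "StateModel", function(x) x@centroids)
setMethod("assignments", "StateModel", function(x) x@assignments)
setMethod("nStates", "StateModel", function(x) x@k)
setMethod("pairLabels", "StateModel", function(x) x@pairNames)

setMethod("meanDwell", "StateOccupancy", function(x) x@meanDwell)
setMethod("fractionTime", "StateOccupancy", function(x) x@fraction)
setMethod("transitionMatrix", "StateOccupancy", function(x) x@transitions)
setMethod("subjectID", "StateOccupancy", function(x) x@subject)
setMethod("groupLabel", "StateOccupancy", function(x) x@group)

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d group(s), %d state(s), C = %d, T = %d, TR = %gs\n",
              length(object@groups), length(object@states), object@nComponents,
              object@T, object@TR))
  for (g in object@groups)
    cat(sprintf("  %-6s n = %d\n", g@name, g@nSubjects))
})

setMethod("show", "SubjectTimecourses", function(object) {
  cat(sprintf("SubjectTimecourses '%s' (%s/%s): %d timepoints x %d components, TR = %gs, stage = %s\n",
              object@subject, object@group, object@session,
              nrow(object@data), ncol(object@data), object@TR, object@stage))
})

setMethod("show", "TaperedWindow", function(object) {
  cat(sprintf("TaperedWindow: %gs = %d TRs (TR = %gs), Gaussian taper sigma = %g TRs\n",
              object@widthS, object@widthTr, object@TR, object@sigmaTr))
})

setMethod("show", "WindowedFNC", function(object) {
  cat(sprintf("WindowedFNC '%s': %d windows x %d pairs (width %d TRs, lambda = %g)\n",
              object@subject, nrow(object@trajectory),
              ncol(object@trajectory), object@widthTr, object@lambda))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel (%s stage): k = %d over %d pairs; inertia = %.4g; %d subject(s) assigned\n",
              object@stage, object@k, ncol(object@centroids),
              object@inertia, length(object@assignments)))
})

setMethod("show", "ElbowCurve", function(object) {
  cat(sprintf("ElbowCurve over k = {%s}: selected k = %d%s\n",
              paste(object@kValues, collapse = ","), object@kSelected,
              if (object@flagged) paste0(" [flagged: ", object@note, "]") else ""))
})

setMethod("show", "StateOccupancy", function(object) {
  cat(sprintf("StateOccupancy '%s' (%s): %d windows\n",
              object@subject, object@group, object@nWindows))
  cat("  fraction:  ", paste(sprintf("%.3f", object@fraction), collapse = " "), "\n")
  cat("  mean dwell:", paste(sprintf("%.2f", object@meanDwell), collapse = " "),
      "(windows)\n")
})
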