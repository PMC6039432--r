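#' Accessors for fretscreen S4 objects
#'
#' Small accessor layer so user code never reaches into slots:
#' \code{wells()} and \code{compoundLibrary()} for campaigns,
#' \code{rejectedRows()} for import rejections, \code{plateQC()},
#' \code{compoundResults()}, \code{stageHits()} and \code{doseFits()} for
#' cascade reports, and \code{ic50()} / \code{kd()} for fits.
#'
#' @param object a fretscreen S4 object
#' @param ... unused
#' @return the requested component (data.frame, numeric, list or character
#'   vector, depending on the accessor)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wells", function(object, ...) standardGeneric("wells"))
#' @rdname accessors
#' @export
setGeneric("compoundLibrary",
           function(object, ...) standardGeneric("compoundLibrary"))
#' @rdname accessors
#' @export
setGeneric("rejectedRows",
           function(object, ...) standardGeneric("rejectedRows"))
#' @rdname accessors
#' @export
setGeneric("plateQC", function(object, ...) standardGeneric("plateQC"))
#' @rdname accessors
#' @export
setGeneric("compoundResults",
           function(object, ...) standardGeneric("compoundResults"))
#' @rdname accessors
#' @param stage which stage list to return (1, 2 or 3)
#' @export
setGeneric("stageHits",
           function(object, stage = 1, ...) standardGeneric("stageHits"))
#' @rdname accessors
#' @export
setGeneric("doseFits", function(object, ...) standardGeneric("doseFits"))
#' @rdname accessors
#' @export
setGeneric("ic50", function(object, ...) standardGeneric("ic50"))
#' @rdname accessors
#' @export
setGeneric("kd", function(object, ...) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object, ...) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setMethod("wells", "ScreeningCampaign", function(object, ...) object@wells)
#' @rdname accessors
#' @export
setMethod("compoundLibrary", "ScreeningCampaign",
          function(object, ...) object@library)
#' @rdname accessors
#' @export
setMethod("rejectedRows", "ScreeningCampaign",
          function(object, ...) object@rejected)
#' @rdname accessors
#' @export
setMethod("plateQC", "CascadeReport", function(object, ...) object@plate_qc)
#' @rdname accessors
#' @export
setMethod("compoundResults", "CascadeReport",
          function(object, ...) object@compounds)
#' @rdname accessors
#' @export
setMethod("stageHits", "CascadeReport", function(object, stage = 1, ...) {
  stopifnot(stage %in% 1:3)
  slot(object, paste0("stage", stage))
})
#' @rdname accessors
#' @export
setMethod("doseFits", "CascadeReport", function(object, ...) object@dose_fits)
#' @rdname accessors
#' @export
setMethod("ic50", "DoseResponseFit", function(object, ...) object@ic50)
#' @rdname accessors
#' @export
setMethod("kd", "FPBindingFit", function(object, ...) object@kd)
#' @rdname accessors
#' @export
setMethod("isConverged", "DoseResponseFit",
          function(object, ...) object@converged)
#' @rdname accessors
#' @export
setMethod("isConverged", "FPBindingFit",
          function(object, ...) object@converged)

#' @rdname accessors
#' @export
setMethod("coef", "DoseResponseFit", function(object, ...) {
  c(top = object@top, bottom = object@bottom, ic50 = object@ic50,
    slope = object@slope)
})
#' @rdname accessors
#' @export
setMethod("coef", "FPBindingFit", function(object, ...) {
  c(p_free = object@p_free, p_bound = object@p_bound, kd = object@kd)
})
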