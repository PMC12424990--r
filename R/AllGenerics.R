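## Generics and accessors. Slots are never reached into from user code;
## these accessors are the supported surface.

#' @name accessors
#' @title Accessors for slicepasef S4 objects
#' @param x an [IonCloud-class], [AcquisitionScheme-class],
#'   [CycleMetrics-class] or [XIC-class] object.
#' @return the corresponding slot value; see the class documentation.
NULL

#' @rdname accessors
#' @export
setGeneric("ions", function(x) standardGeneric("ions"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("mzRange", function(x) standardGeneric("mzRange"))
#' @rdname accessors
#' @export
setGeneric("imRange", function(x) standardGeneric("imRange"))
#' @rdname accessors
#' @export
setGeneric("gradientLength", function(x) standardGeneric("gradientLength"))
#' @rdname accessors
#' @export
setGeneric("nIons", function(x) standardGeneric("nIons"))
#' @rdname accessors
#' @export
setGeneric("schemeFrames", function(x) standardGeneric("schemeFrames"))
#' @rdname accessors
#' @export
setGeneric("schemeSteps", function(x) standardGeneric("schemeSteps"))
#' @rdname accessors
#' @export
setGeneric("schemeLabel", function(x) standardGeneric("schemeLabel"))
#' @rdname accessors
#' @export
setGeneric("nSubcycles", function(x) standardGeneric("nSubcycles"))
#' @rdname accessors
#' @export
setGeneric("cycleTimeMs", function(x) standardGeneric("cycleTimeMs"))
#' @rdname accessors
#' @export
setGeneric("dutyCycle", function(x) standardGeneric("dutyCycle"))
#' @rdname accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))
#' @rdname accessors
#' @export
setGeneric("pointsPerPeak", function(x) standardGeneric("pointsPerPeak"))
#' @rdname accessors
#' @export
setGeneric("xicTrace", function(x) standardGeneric("xicTrace"))
#' @rdname accessors
#' @export
setGeneric("xicApex", function(x) standardGeneric("xicApex"))
#' @rdname accessors
#' @export
setGeneric("pointsAtFwhm", function(x) standardGeneric("pointsAtFwhm"))

## IonCloud ------------------------------------------------------------------

#' @rdname accessors
setMethod("ions", "IonCloud", function(x) x@ions)
#' @rdname accessors
setMethod("fragments", "IonCloud", function(x) x@fragments)
#' @rdname accessors
setMethod("mzRange", "IonCloud", function(x) x@mzRange)
#' @rdname accessors
setMethod("imRange", "IonCloud", function(x) x@imRange)
#' @rdname accessors
setMethod("gradientLength", "IonCloud", function(x) x@gradientLengthS)
#' @rdname accessors
setMethod("nIons", "IonCloud", function(x) nrow(x@ions))

setMethod("show", "IonCloud", function(object) {
  io <- object@ions
  cat(sprintf("IonCloud: %d precursors, %d fragment ions\n",
              nrow(io), nrow(object@fragments)))
  cat(sprintf("  m/z %.1f-%.1f Th, 1/K0 %.3f-%.3f, gradient %.0f s\n",
              object@mzRange[1], object@mzRange[2],
              object@imRange[1], object@imRange[2], object@gradientLengthS))
  if (nrow(io)) {
    tab <- table(io$charge)
    cat("  charge states: ",
        paste(sprintf("%s+ (%d)", names(tab), tab), collapse = ", "), "\n",
        sep = "")
  }
})

## AcquisitionScheme ---------------------------------------------------------

#' @rdname accessors
setMethod("schemeFrames", "AcquisitionScheme", function(x) x@frames)
#' @rdname accessors
setMethod("schemeSteps", "AcquisitionScheme", function(x) x@steps)
#' @rdname accessors
setMethod("schemeLabel", "AcquisitionScheme", function(x) x@label)
#' @rdname accessors
setMethod("mzRange", "AcquisitionScheme", function(x) x@mzRange)
#' @rdname accessors
setMethod("imRange", "AcquisitionScheme", function(x) x@imRange)
#' @rdname accessors
setMethod("nSubcycles", "AcquisitionScheme",
          function(x) length(unique(x@frames$subcycle)))

setMethod("show", "AcquisitionScheme", function(object) {
  fr <- object@frames
  ms2 <- fr[fr$kind == "MS2", , drop = FALSE]
  cat(sprintf("AcquisitionScheme '%s'\n", object@label))
  cat(sprintf("  %d subcycle(s), %d frame(s) (%d MS2), %d slice-step(s)\n",
              length(unique(fr$subcycle)), nrow(fr), nrow(ms2),
              nrow(object@steps)))
  cat(sprintf("  m/z %.1f-%.1f Th, 1/K0 %.3f-%.3f\n",
              object@mzRange[1], object@mzRange[2],
              object@imRange[1], object@imRange[2]))
  cat(sprintf("  cycle time %.0f ms (fill times incl. MS1 and repeats)\n",
              sum(fr$fill_time_ms * fr$repeats)))
})

## CycleMetrics ---------------------------------------------------------------

#' @rdname accessors
setMethod("cycleTimeMs", "CycleMetrics", function(x) x@cycleTimeMs)
#' @rdname accessors
setMethod("dutyCycle", "CycleMetrics", function(x) x@dutyCycle)
#' @rdname accessors
setMethod("coverage", "CycleMetrics", function(x) x@coverage)
#' @rdname accessors
setMethod("pointsPerPeak", "CycleMetrics", function(x) x@pointsPerPeak)

setMethod("show", "CycleMetrics", function(object) {
  cat("CycleMetrics\n")
  cat(sprintf("  cycle time      : %.1f ms\n", object@cycleTimeMs))
  cat(sprintf("  MS/MS duty cycle: %.1f %% (intensity-weighted), %.1f %% (per ion)\n",
              100 * object@dutyCycle, 100 * object@dutyCycleCount))
  cat(sprintf("  coverage        : %.1f %% (intensity), %.1f %% (per ion)\n",
              100 * object@coverage, 100 * object@coverageCount))
  cat(sprintf("  points per peak : %.2f\n", object@pointsPerPeak))
})

## XIC ------------------------------------------------------------------------

#' @rdname accessors
setMethod("xicTrace", "XIC", function(x) x@trace)
#' @rdname accessors
setMethod("xicApex", "XIC", function(x) x@apex)
#' @rdname accessors
setMethod("pointsAtFwhm", "XIC", function(x) x@pointsAtFwhm)

setMethod("show", "XIC", function(object) {
  cat(sprintf("XIC: %d cycles, apex %.3g, area %.3g, %d points at FWHM%s\n",
              nrow(object@trace), object@apex, object@area,
              object@pointsAtFwhm,
              if (object@allZero) " [no signal]" else ""))
})
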