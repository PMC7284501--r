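#' @rdname PerfusateSpec-class
#' @param object,x a \linkS4class{PerfusateSpec} or
#'   \linkS4class{PerfusionExperiment}
#' @export
setGeneric("Cperf", function(x) standardGeneric("Cperf"))

#' @rdname PerfusateSpec-class
#' @export
setGeneric("CstarPerf", function(x) standardGeneric("CstarPerf"))

#' @rdname PerfusionExperiment-class
#' @export
setGeneric("perfusionSamples", function(x) standardGeneric("perfusionSamples"))

#' @rdname PerfusionExperiment-class
#' @export
setGeneric("perfusate", function(x) standardGeneric("perfusate"))

#' @rdname CalibrationCurve-class
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))

#' @rdname CalibrationCurve-class
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))

#' @rdname CalibrationCurve-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname CalibrationCurve-class
#' @export
setGeneric("loqFmol", function(x) standardGeneric("loqFmol"))

#' @rdname PerfusateSpec-class
#' @export
setMethod("Cperf", "PerfusateSpec", function(x) x@Cperf)

#' @rdname PerfusateSpec-class
#' @export
setMethod("CstarPerf", "PerfusateSpec", function(x) x@CstarPerf)

#' @rdname PerfusionExperiment-class
#' @export
setMethod("perfusionSamples", "PerfusionExperiment", function(x) x@samples)

#' @rdname PerfusionExperiment-class
#' @export
setMethod("perfusate", "PerfusionExperiment", function(x) x@perfusate)

#' @rdname PerfusionExperiment-class
#' @export
setMethod("Cperf", "PerfusionExperiment", function(x) x@perfusate@Cperf)

#' @rdname PerfusionExperiment-class
#' @export
setMethod("CstarPerf", "PerfusionExperiment", function(x) x@perfusate@CstarPerf)

#' @rdname CalibrationCurve-class
#' @export
setMethod("curveSlope", "CalibrationCurve", function(x) x@slope)

#' @rdname CalibrationCurve-class
#' @export
setMethod("curveIntercept", "CalibrationCurve", function(x) x@intercept)

#' @rdname CalibrationCurve-class
#' @export
setMethod("rSquared", "CalibrationCurve", function(x) x@rSquared)

#' @rdname CalibrationCurve-class
#' @export
setMethod("loqFmol", "CalibrationCurve", function(x) x@loqFmol)

#' @rdname PerfusateSpec-class
#' @export
setMethod("show", "PerfusateSpec", function(object) {
  cat("PerfusateSpec\n")
  cat(sprintf("  Cperf:      %g dpm/uL\n", object@Cperf))
  cat(sprintf("  Cstar_perf: %g dpm/uL\n", object@CstarPerf))
  cat(sprintf("  flow rate:  %g mL/min\n", object@flowRate))
  if (length(object@inhibitors) > 0)
    cat("  inhibitors:", paste(sprintf("%s (%g uM)", names(object@inhibitors),
                                       object@inhibitors), collapse = ", "),
        "\n")
  else cat("  inhibitors: none\n")
  invisible(NULL)
})

#' @rdname PerfusionExperiment-class
#' @export
setMethod("show", "PerfusionExperiment", function(object) {
  s <- object@samples
  cat(sprintf("PerfusionExperiment: %d sample(s)\n", nrow(s)))
  if (nrow(s) > 0) {
    cat(sprintf("  species: %s | regions: %s | tracers: %s\n",
                paste(unique(s$species), collapse = ", "),
                paste(unique(s$region), collapse = ", "),
                paste(unique(s$tracer), collapse = ", ")))
    cat(sprintf("  groups: %s | treatments: %s\n",
                paste(unique(s$group), collapse = ", "),
                paste(unique(s$treatment), collapse = ", ")))
  }
  show(object@perfusate)
  invisible(NULL)
})

#' @rdname SimScenario-class
#' @param object a \linkS4class{SimScenario}
#' @export
setMethod("show", "SimScenario", function(object) {
  cat(sprintf("SimScenario (%s)\n", object@species))
  cat(sprintf("  regions: %s\n",
              paste(object@regions$region, collapse = ", ")))
  cat(sprintf("  transporters: %s\n",
              if (nrow(object@transporters) == 0) "none"
              else paste(sprintf("%s (a=%g)", object@transporters$name,
                                 object@transporters$activity),
                         collapse = ", ")))
  cat(sprintf("  design: %d cell(s), %d animals/region; biological CV %g\n",
              nrow(object@design), sum(object@design$n), object@biologicalCV))
  cat(sprintf("  T = %g s (flow marker %g s), seed %d\n", object@T,
              object@flowT, as.integer(object@seed)))
  invisible(NULL)
})

#' @rdname CalibrationCurve-class
#' @export
setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve\n")
  cat(sprintf("  area_ratio = %.6g + %.6g * fmol (weighting: %s, n = %d)\n",
              object@intercept, object@slope, object@weighting,
              as.integer(object@nStandards)))
  cat(sprintf("  r^2 = %.6g, LOQ = %g fmol\n", object@rSquared,
              object@loqFmol))
  invisible(NULL)
})
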