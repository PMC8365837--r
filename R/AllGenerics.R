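#' @describeIn RegionTimeseries the volumes x regions data matrix.
#' @param x,object an object of the documented class.
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @describeIn RegionTimeseries the repetition time in seconds.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @describeIn RegionTimeseries the ordered region labels.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @describeIn RegionTimeseries the subject identifier.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @describeIn RegionTimeseries number of volumes (rows).
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @describeIn RegionTimeseries number of regions (columns).
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

setMethod("tsMatrix", "RegionTimeseries", function(x) x@data)
setMethod("repetitionTime", "RegionTimeseries", function(x) x@tr)
setMethod("regionLabels", "RegionTimeseries", function(x) colnames(x@data))
setMethod("subjectId", "RegionTimeseries", function(x) x@subjectId)
setMethod("nVolumes", "RegionTimeseries", function(x) nrow(x@data))
setMethod("nRegions", "RegionTimeseries", function(x) ncol(x@data))

setMethod("show", "RegionTimeseries", function(object) {
  cat(sprintf("RegionTimeseries '%s': %d volumes x %d regions, TR = %g s\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@tr))
  lab <- colnames(object@data)
  cat("  regions: ", paste(head(lab, 4), collapse = ", "),
      if (length(lab) > 4) sprintf(", ... (%d more)", length(lab) - 4L),
      "\n", sep = "")
})

setMethod("show", "EventTrain", function(object) {
  cat(sprintf("EventTrain '%s': %d events", object@spikeType,
              length(object@onsets)))
  if (length(object@onsets))
    cat(sprintf(" in [%.2f, %.2f] s", min(object@onsets),
                max(object@onsets + object@durations)))
  cat("\n")
})

setMethod("length", "EventTrain", function(x) length(x@onsets))

setMethod("show", "HRFBasis", function(object) {
  cat(sprintf(paste0("HRFBasis: canonical double-gamma + temporal/dispersion",
                     " derivatives\n  dt = %g s, duration = %g s, %d samples,",
                     " peak at %.2f s\n"),
              object@dt, object@duration, length(object@canonical),
              object@sampleTimes[which.max(object@canonical)]))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes x %d regressors (TR = %g s)\n",
              nrow(object@data), ncol(object@data), object@tr))
  cat("  columns:", paste(colnames(object@data), collapse = ", "), "\n")
})

setMethod("show", "CentralityCurve", function(object) {
  cat(sprintf("CentralityCurve (%s): %d densities in [%g, %g] x %d regions\n",
              object@metric, length(object@densities),
              min(object@densities), max(object@densities),
              ncol(object@values)))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison%s [%s, %s]\n",
              if (nzchar(object@region)) paste0(" ", object@region) else "",
              object@metric, object@method))
  cat(sprintf("  median difference = %.4g, p = %.4g, r = %.3f (n1 = %d, n2 = %d, %d permutations)\n",
              object@observedDiff, object@pValue, object@effectSizeR,
              object@n1, object@n2, as.integer(object@nPermutations)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d patients vs %d controls, %d regions x %d",
                     " volumes, TR = %g s\n  hub %s/%s (+%g rho on %d targets),",
                     " IED amplitude %g on %d regions, %g-%g IEDs/session\n"),
              object@nPatients, object@nControls, object@nRegions,
              object@nVolumes, object@tr, object@hubRegions[1],
              object@hubRegions[2], object@hubEffect,
              length(object@hubTargets), object@iedAmplitude,
              length(object@iedRegions), object@iedCountRange[1],
              object@iedCountRange[2]))
})
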