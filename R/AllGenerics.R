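#' @name boldcvr-accessors
#' @title Accessors for boldcvr classes
#' @description Slot accessors for the package's S4 containers. Use these
#'   rather than \code{@} access.
#' @param x an object.
NULL

#' @rdname boldcvr-accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname boldcvr-accessors
#' @export
setMethod("seriesValues", "SampledSeries", function(x) x@values)

#' @rdname boldcvr-accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname boldcvr-accessors
#' @export
setMethod("samplingInterval", "SampledSeries", function(x) x@dt)
#' @rdname boldcvr-accessors
#' @export
setMethod("samplingInterval", "BoldRun", function(x) x@dt)

#' @rdname boldcvr-accessors
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))
#' @rdname boldcvr-accessors
#' @export
setMethod("seriesTimes", "SampledSeries",
          function(x) x@t0 + (seq_along(x@values) - 1) * x@dt)

#' @rdname boldcvr-accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname boldcvr-accessors
#' @export
setMethod("boldData", "BoldRun", function(x) x@data)

#' @rdname boldcvr-accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))
#' @rdname boldcvr-accessors
#' @export
setMethod("voxelGrid", "BoldRun", function(x) x@grid)
#' @rdname boldcvr-accessors
#' @export
setMethod("voxelGrid", "BrainMask", function(x) x@grid)
#' @rdname boldcvr-accessors
#' @export
setMethod("voxelGrid", "CVRResult", function(x) x@grid)
#' @rdname boldcvr-accessors
#' @export
setMethod("voxelGrid", "GroundTruth", function(x) x@grid)

#' @rdname boldcvr-accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname boldcvr-accessors
#' @export
setMethod("maskArray", "BrainMask", function(x) x@mask)

#' @rdname boldcvr-accessors
#' @export
setGeneric("cvrMap", function(x) standardGeneric("cvrMap"))
#' @rdname boldcvr-accessors
#' @export
setMethod("cvrMap", "CVRResult", function(x) x@cvr)
#' @rdname boldcvr-accessors
#' @export
setMethod("cvrMap", "GroundTruth", function(x) x@cvr)

#' @rdname boldcvr-accessors
#' @export
setGeneric("delayMap", function(x) standardGeneric("delayMap"))
#' @rdname boldcvr-accessors
#' @export
setMethod("delayMap", "CVRResult", function(x) x@delay)
#' @rdname boldcvr-accessors
#' @export
setMethod("delayMap", "GroundTruth", function(x) x@delay)

#' @rdname boldcvr-accessors
#' @export
setGeneric("r2Map", function(x) standardGeneric("r2Map"))
#' @rdname boldcvr-accessors
#' @export
setMethod("r2Map", "CVRResult", function(x) x@r2)

#' @rdname boldcvr-accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))
#' @rdname boldcvr-accessors
#' @export
setMethod("tMap", "CVRResult", function(x) x@tvalue)

#' @rdname boldcvr-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname boldcvr-accessors
#' @export
setMethod("validMask", "CVRResult", function(x) x@valid)

#' @rdname boldcvr-accessors
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))
#' @rdname boldcvr-accessors
#' @export
setMethod("tissueLabels", "GroundTruth", function(x) x@labels)

#' @rdname boldcvr-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname boldcvr-accessors
#' @export
setMethod("groundTruth", "SyntheticRun", function(x) x@truth)

setMethod("show", "SampledSeries", function(object) {
  cat(sprintf("SampledSeries '%s': %d samples, dt = %g s, t0 = %g s\n",
              object@label, length(object@values), object@dt, object@t0))
})

setMethod("show", "BoldRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldRun %s [%s/%s]: %dx%dx%d voxels x %d frames, dt = %g s, voxel %s mm\n",
              object@subjectID, object@paradigm, object@session,
              d[1], d[2], d[3], d[4], object@dt,
              paste(object@grid@voxelSize, collapse = "x")))
})

setMethod("show", "CVRResult", function(object) {
  cat(sprintf("CVRResult %s [%s/%s]: %d/%d valid voxels, regressor = %s\n",
              object@subjectID, object@paradigm, object@session,
              sum(object@valid), length(object@valid), object@regressorKind))
  cv <- object@cvr[object@valid]
  if (length(cv))
    cat(sprintf("  CVR median %.4g, delay range [%.3g, %.3g] s\n",
                median(cv), min(object@delay[object@valid]),
                max(object@delay[object@valid])))
})

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol [%s]: %d blocks, total %g s\n",
              object@paradigm, nrow(object@blocks), sum(object@blocks$duration_s)))
  print(object@blocks)
})

setMethod("show", "RepeatabilityReport", function(object) {
  cat(sprintf("RepeatabilityReport '%s': n = %d subjects\n",
              object@condition, length(object@perSubjectICC)))
  cat(sprintf("  mean ICC(C,1) %.3f | within r %.3f | between r %.3f | differential %.3f\n",
              mean(object@perSubjectICC, na.rm = TRUE), object@withinCorr,
              object@betweenCorr, object@differentialCorr))
})
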