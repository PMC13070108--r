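#' Spatial geometry of a voxel grid
#'
#' Holds the array shape, voxel size in millimetres and an origin offset for
#' volumes handled by the pipeline. Smoothing kernels are specified in mm and
#' converted to voxels through this geometry.
#'
#' @slot shape integer(3), array dimensions (x, y, z), each >= 1.
#' @slot voxelSize numeric(3), voxel edge length in mm, each > 0.
#' @slot origin numeric(3), origin offset in mm (bookkeeping only).
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", voxelSize = "numeric", origin = "numeric"),
  prototype(shape = c(1L, 1L, 1L), voxelSize = c(1, 1, 1), origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "shape must be 3 integers >= 1")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive reals (mm)")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    if (length(msg)) msg else TRUE
  })

#' @param shape integer(3) array dimensions.
#' @param voxelSize numeric(3) voxel size in mm.
#' @param origin numeric(3) origin offset in mm.
#' @rdname VoxelGrid-class
#' @export
VoxelGrid <- function(shape, voxelSize = c(3, 3, 3), origin = c(0, 0, 0)) {
  new("VoxelGrid", shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' A uniformly sampled scalar timeseries
#'
#' The carrier type for every 1-D signal in the pipeline: single-voxel BOLD
#' series, end-tidal CO2, the global signal, motion parameters and derived
#' confounds. Samples are taken at \code{t0 + (i-1) * dt} seconds.
#'
#' @slot values numeric vector of samples (NA marks missing on ingest).
#' @slot dt sampling interval in seconds, > 0.
#' @slot t0 time of the first sample in seconds.
#' @slot label short description, e.g. \code{"etco2"}.
#' @export
setClass("SampledSeries",
  representation(values = "numeric", dt = "numeric", t0 = "numeric",
                 label = "character"),
  prototype(values = c(0, 0), dt = 1, t0 = 0, label = ""),
  validity = function(object) {
    msg <- character()
    if (length(object@values) < 2L) msg <- c(msg, "need at least 2 samples")
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
      msg <- c(msg, "dt must be a single positive real (seconds)")
    if (length(object@t0) != 1L || !is.finite(object@t0))
      msg <- c(msg, "t0 must be a single finite real")
    if (length(msg)) msg else TRUE
  })

#' @param values numeric samples.
#' @param dt sampling interval (s).
#' @param t0 time of first sample (s).
#' @param label series label.
#' @rdname SampledSeries-class
#' @export
SampledSeries <- function(values, dt, t0 = 0, label = "") {
  new("SampledSeries", values = as.numeric(values), dt = as.numeric(dt),
      t0 = as.numeric(t0), label = as.character(label)[1])
}

#' A 4-D BOLD fMRI run
#'
#' One functional acquisition: a 4-D sample grid (x, y, z, t) with spatial
#' geometry, repetition interval, vascular paradigm and session labels.
#'
#' @slot data 4-D numeric array (x, y, z, t).
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot dt repetition interval in seconds (default acquisition 0.878 s).
#' @slot paradigm one of "CO2", "BH", "RS".
#' @slot session one of "test", "retest".
#' @slot subjectID subject identifier.
#' @export
setClass("BoldRun",
  representation(data = "array", grid = "VoxelGrid", dt = "numeric",
                 paradigm = "character", session = "character",
                 subjectID = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 4L) msg <- c(msg, "data must be a 4-D array (x,y,z,t)")
    else {
      if (d[4] < 2L) msg <- c(msg, "time dimension must have >= 2 frames")
      if (!identical(as.integer(d[1:3]), object@grid@shape))
        msg <- c(msg, "spatial dimensions disagree with grid shape")
    }
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
      msg <- c(msg, "dt must be a single positive real (seconds)")
    if (!object@paradigm %in% c("CO2", "BH", "RS"))
      msg <- c(msg, "paradigm must be one of CO2, BH, RS")
    if (!object@session %in% c("test", "retest"))
      msg <- c(msg, "session must be test or retest")
    if (anyNA(object@data) || any(!is.finite(object@data)))
      msg <- c(msg, "data must contain no non-finite samples")
    if (length(msg)) msg else TRUE
  })

#' @param data 4-D numeric array.
#' @param grid a \linkS4class{VoxelGrid}; defaults to 3 mm isotropic.
#' @param dt repetition interval (s).
#' @param paradigm paradigm label.
#' @param session session label.
#' @param subjectID subject identifier.
#' @rdname BoldRun-class
#' @export
BoldRun <- function(data, grid = NULL, dt = 0.878, paradigm = "CO2",
                    session = "test", subjectID = "sub-01") {
  data <- as.array(data)
  if (is.null(grid)) grid <- VoxelGrid(dim(data)[1:3])
  new("BoldRun", data = data, grid = grid, dt = as.numeric(dt),
      paradigm = paradigm, session = session, subjectID = subjectID)
}

#' Brain voxel mask
#'
#' @slot mask 3-D logical array.
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot kind "epi" (intensity heuristic) or "provided".
#' @export
setClass("BrainMask",
  representation(mask = "array", grid = "VoxelGrid", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
      msg <- c(msg, "mask must be a 3-D logical array")
    else if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
    else if (!identical(as.integer(dim(object@mask)), object@grid@shape))
      msg <- c(msg, "mask dimensions disagree with grid shape")
    if (!object@kind %in% c("epi", "provided"))
      msg <- c(msg, "kind must be epi or provided")
    if (length(msg)) msg else TRUE
  })

#' @param mask 3-D logical array.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param kind mask provenance.
#' @rdname BrainMask-class
#' @export
BrainMask <- function(mask, grid = NULL, kind = "provided") {
  mask <- array(as.logical(mask), dim(mask))
  if (is.null(grid)) grid <- VoxelGrid(dim(mask))
  new("BrainMask", mask = mask, grid = grid, kind = kind)
}

#' Stimulus protocol of a vascular paradigm
#'
#' An ordered list of (phase name, duration s, level) blocks. The shipped
#' paradigms all span 5 minutes (300 s).
#'
#' @slot blocks data.frame with columns name, duration_s, level.
#' @slot paradigm "CO2", "BH" or "RS".
#' @export
setClass("StimulusProtocol",
  representation(blocks = "data.frame", paradigm = "character"),
  validity = function(object) {
    msg <- character()
    b <- object@blocks
    if (!all(c("name", "duration_s", "level") %in% names(b)))
      msg <- c(msg, "blocks needs columns name, duration_s, level")
    else if (any(b$duration_s <= 0)) msg <- c(msg, "block durations must be > 0")
    if (!object@paradigm %in% c("CO2", "BH", "RS"))
      msg <- c(msg, "paradigm must be one of CO2, BH, RS")
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a synthetic subject
#'
#' Latent quantities the pipeline estimates, recorded at generation time:
#' reactivity amplitude (% BOLD per regressor unit), hemodynamic delay (s),
#' tissue labels (0 background, 1 GM, 2 WM, 3 CSF), per-voxel drift
#' coefficients, motion coupling weights and noise SD.
#'
#' @slot cvr 3-D numeric array, %/unit.
#' @slot delay 3-D numeric array, seconds.
#' @slot labels 3-D integer array of tissue labels.
#' @slot baseline 3-D numeric array of baseline intensities.
#' @slot driftCoeffs 4-D array (x,y,z,order) of polynomial drift coefficients.
#' @slot motionCoupling 4-D array (x,y,z,6) of per-parameter coupling weights.
#' @slot noiseSD 3-D numeric array, raw-intensity noise SD (> 0 inside brain).
#' @slot grid a \linkS4class{VoxelGrid}.
#' @export
setClass("GroundTruth",
  representation(cvr = "array", delay = "array", labels = "array",
                 baseline = "array", driftCoeffs = "array",
                 motionCoupling = "array", noiseSD = "array",
                 grid = "VoxelGrid"),
  validity = function(object) {
    msg <- character()
    sh <- object@grid@shape
    for (nm in c("cvr", "delay", "labels", "baseline", "noiseSD"))
      if (!identical(as.integer(dim(slot(object, nm))[1:3]), sh))
        msg <- c(msg, paste(nm, "does not match grid shape"))
    inside <- object@labels > 0L
    if (any(object@noiseSD[inside] < 0))
      msg <- c(msg, "noiseSD must be >= 0 inside brain")
    if (length(msg)) msg else TRUE
  })

#' One synthetic run with its generating truth
#'
#' @slot bold a \linkS4class{BoldRun}.
#' @slot etco2 end-tidal CO2 trace at 1 Hz (\linkS4class{SampledSeries}).
#' @slot motion list of 6 motion-parameter series at the BOLD rate
#'   (3 translations mm, 3 rotations rad).
#' @slot truth the shared \linkS4class{GroundTruth}.
#' @slot seed integer seed the run was drawn from.
#' @export
setClass("SyntheticRun",
  representation(bold = "BoldRun", etco2 = "SampledSeries", motion = "list",
                 truth = "GroundTruth", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@motion) != 6L)
      msg <- c(msg, "motion must hold exactly 6 series")
    nt <- dim(object@bold@data)[4]
    if (any(vapply(object@motion, function(s) length(s@values), 1L) != nt))
      msg <- c(msg, "motion series length must equal BOLD frame count")
    if (length(msg)) msg else TRUE
  })

#' Per-run CVR maps
#'
#' Voxel-wise results of one fitted run: CVR amplitude (% BOLD per regressor
#' unit), hemodynamic delay, model R^2, regressor t-value, regressor--BOLD
#' correlation at the selected lag, and a validity mask. Invalid voxels carry
#' NA in every map.
#'
#' @slot cvr 3-D numeric array.
#' @slot delay 3-D numeric array (s).
#' @slot r2 3-D numeric array in [0, 1] where valid.
#' @slot tvalue 3-D numeric array.
#' @slot rcorr 3-D numeric array, regressor--BOLD Pearson r at selected lag.
#' @slot valid 3-D logical array.
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot paradigm,session,subjectID run identity labels.
#' @slot regressorKind "etco2" (units %/mmHg) or "global_signal" (unitless %/%).
#' @slot regressorShift seconds the ET-CO2 regressor was moved when aligned
#'   to the global signal; voxel delays are relative to the shifted regressor,
#'   so \code{delay + regressorShift} approximates absolute physiological delay.
#' @slot configDigest md5 digest of the generating configuration.
#' @export
setClass("CVRResult",
  representation(cvr = "array", delay = "array", r2 = "array",
                 tvalue = "array", rcorr = "array", valid = "array",
                 grid = "VoxelGrid", paradigm = "character",
                 session = "character", subjectID = "character",
                 regressorKind = "character", regressorShift = "numeric",
                 configDigest = "character"),
  validity = function(object) {
    msg <- character()
    sh <- object@grid@shape
    for (nm in c("cvr", "delay", "r2", "tvalue", "rcorr", "valid"))
      if (!identical(as.integer(dim(slot(object, nm))), sh))
        msg <- c(msg, paste(nm, "does not match grid shape"))
    v <- object@valid
    r2v <- object@r2[v]
    if (length(r2v) && any(!is.na(r2v) & (r2v < -1e-9 | r2v > 1 + 1e-9)))
      msg <- c(msg, "r2 must lie in [0,1] where valid")
    if (length(msg)) msg else TRUE
  })

#' Per-condition repeatability summary
#'
#' @slot perSubjectICC spatial ICC(C,1) per subject.
#' @slot fisherZ Fisher z-transformed ICC values.
#' @slot withinCorr mean within-subject map correlation.
#' @slot betweenCorr mean between-subject map correlation.
#' @slot differentialCorr withinCorr - betweenCorr (exactly).
#' @slot covMap 3-D coefficient-of-variation map, capped at 1.
#' @slot absdiffMap 3-D median-scaled absolute test-retest difference map.
#' @slot condition free-text condition label.
#' @export
setClass("RepeatabilityReport",
  representation(perSubjectICC = "numeric", fisherZ = "numeric",
                 withinCorr = "numeric", betweenCorr = "numeric",
                 differentialCorr = "numeric", covMap = "array",
                 absdiffMap = "array", condition = "character"))
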