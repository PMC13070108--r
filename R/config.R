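#' Pipeline design-parameter configuration
#'
#' Every tunable stage of the CVR processing chain in one object. Defaults
#' reproduce the standard settings: 5 mm smoothing, first-order detrending,
#' 116.4 mHz low-pass, 2x temporal upsampling, overall-mean PSC baseline,
#' no delay alignment, no motion-confounds, MAD z threshold 10, no
#' quality-based exclusion, no normalization, whole-brain analysis,
#' EPI-mask, 15 s initial trim.
#'
#' @slot fwhm_mm Gaussian smoothing FWHM in mm (>= 0; 0 = no smoothing).
#' @slot detrend_order polynomial detrend degree 0--3 (0 = none).
#' @slot lowpass_mhz low-pass cutoff in mHz (Inf = no filter).
#' @slot upsample_factor temporal upsampling factor 1--4.
#' @slot baseline_strategy "overall_mean" or "initial_window".
#' @slot regressor_kind "etco2" or "global_signal".
#' @slot max_delay_s voxel-wise delay bound in s (0 = no alignment; Inf = unbounded).
#' @slot confound_corr_threshold motion-confound screening threshold in [0,1]
#'   (confound kept iff |r| with regressor is strictly below; 0 = none kept).
#' @slot mad_z_threshold modified-z threshold of the MAD outlier filter (> 0).
#' @slot quality_metric "none", "r2", "tvalue", "tsnr" or "fmap".
#' @slot quality_quantile fraction of lowest-metric voxels removed, in (0,1).
#' @slot normalization "none", "GM", "WM", "CSF" or "WB".
#' @slot tissue_restrict "WB", "GM", "WM" or "CSF".
#' @slot mask_kind "epi" or "provided".
#' @slot trim_initial_s seconds discarded at run start after alignment.
#' @slot delay_median_filter logical; 3x3x3 median-filter delays then re-fit.
#' @slot seed integer seed for any stochastic step.
#' @export
setClass("PipelineConfig",
  representation(
    fwhm_mm = "numeric", detrend_order = "integer", lowpass_mhz = "numeric",
    upsample_factor = "integer", baseline_strategy = "character",
    regressor_kind = "character", max_delay_s = "numeric",
    confound_corr_threshold = "numeric", mad_z_threshold = "numeric",
    quality_metric = "character", quality_quantile = "numeric",
    normalization = "character", tissue_restrict = "character",
    mask_kind = "character", trim_initial_s = "numeric",
    delay_median_filter = "logical", seed = "integer"),
  prototype(
    fwhm_mm = 5, detrend_order = 1L, lowpass_mhz = 116.4,
    upsample_factor = 2L, baseline_strategy = "overall_mean",
    regressor_kind = "etco2", max_delay_s = 0,
    confound_corr_threshold = 0, mad_z_threshold = 10,
    quality_metric = "none", quality_quantile = 0.10,
    normalization = "none", tissue_restrict = "WB",
    mask_kind = "epi", trim_initial_s = 15,
    delay_median_filter = FALSE, seed = 1L),
  validity = function(object) .validateConfig(object))

.configRanges <- list(
  fwhm_mm = "real >= 0",
  detrend_order = "integer in 0..3",
  lowpass_mhz = "positive real or Inf",
  upsample_factor = "integer in 1..4",
  baseline_strategy = "one of overall_mean, initial_window",
  regressor_kind = "one of etco2, global_signal",
  max_delay_s = "real >= 0 or Inf",
  confound_corr_threshold = "real in [0,1]",
  mad_z_threshold = "positive real",
  quality_metric = "one of none, r2, tvalue, tsnr, fmap",
  quality_quantile = "real in (0,1)",
  normalization = "one of none, GM, WM, CSF, WB",
  tissue_restrict = "one of WB, GM, WM, CSF",
  mask_kind = "one of epi, provided",
  trim_initial_s = "real >= 0",
  delay_median_filter = "logical",
  seed = "integer")

.validateConfig <- function(x) {
  bad <- function(key) sprintf("%s out of range: must be %s", key,
                               .configRanges[[key]])
  msg <- character()
  chk <- function(ok, key) if (!isTRUE(ok)) msg <<- c(msg, bad(key))
  chk(length(x@fwhm_mm) == 1 && is.finite(x@fwhm_mm) && x@fwhm_mm >= 0, "fwhm_mm")
  chk(length(x@detrend_order) == 1 && !is.na(x@detrend_order) &&
        x@detrend_order >= 0L && x@detrend_order <= 3L, "detrend_order")
  chk(length(x@lowpass_mhz) == 1 && !is.na(x@lowpass_mhz) && x@lowpass_mhz > 0,
      "lowpass_mhz")
  chk(length(x@upsample_factor) == 1 && !is.na(x@upsample_factor) &&
        x@upsample_factor >= 1L && x@upsample_factor <= 4L, "upsample_factor")
  chk(x@baseline_strategy %in% c("overall_mean", "initial_window"),
      "baseline_strategy")
  chk(x@regressor_kind %in% c("etco2", "global_signal"), "regressor_kind")
  chk(length(x@max_delay_s) == 1 && !is.na(x@max_delay_s) && x@max_delay_s >= 0,
      "max_delay_s")
  chk(length(x@confound_corr_threshold) == 1 &&
        is.finite(x@confound_corr_threshold) &&
        x@confound_corr_threshold >= 0 && x@confound_corr_threshold <= 1,
      "confound_corr_threshold")
  chk(length(x@mad_z_threshold) == 1 && is.finite(x@mad_z_threshold) &&
        x@mad_z_threshold > 0, "mad_z_threshold")
  chk(x@quality_metric %in% c("none", "r2", "tvalue", "tsnr", "fmap"),
      "quality_metric")
  chk(length(x@quality_quantile) == 1 && is.finite(x@quality_quantile) &&
        x@quality_quantile > 0 && x@quality_quantile < 1, "quality_quantile")
  chk(x@normalization %in% c("none", "GM", "WM", "CSF", "WB"), "normalization")
  chk(x@tissue_restrict %in% c("WB", "GM", "WM", "CSF"), "tissue_restrict")
  chk(x@mask_kind %in% c("epi", "provided"), "mask_kind")
  chk(length(x@trim_initial_s) == 1 && is.finite(x@trim_initial_s) &&
        x@trim_initial_s >= 0, "trim_initial_s")
  chk(length(x@delay_median_filter) == 1 && !is.na(x@delay_median_filter),
      "delay_median_filter")
  if (length(msg)) msg else TRUE
}

#' Build a pipeline configuration
#'
#' Unspecified parameters take their defaults (see
#' \linkS4class{PipelineConfig}). Every value is range-checked; out-of-range
#' values raise an error naming the key and its legal range.
#'
#' @param ... named parameters overriding the defaults, e.g.
#'   \code{fwhm_mm = 0}, \code{lowpass_mhz = Inf}.
#' @return a \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig()              # all defaults
#' cfg2 <- pipelineConfig(fwhm_mm = 0, max_delay_s = 15)
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop("all configuration arguments must be named")
  legal <- slotNames("PipelineConfig")
  unknown <- setdiff(names(args), legal)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  intKeys <- c("detrend_order", "upsample_factor", "seed")
  for (k in names(args)) {
    v <- args[[k]]
    if (k %in% intKeys) {
      if (length(v) == 1 && is.numeric(v) && is.finite(v) && v == round(v))
        v <- as.integer(v)
      else if (!is.integer(v))
        stop(sprintf("%s out of range: must be %s", k, .configRanges[[k]]))
    }
    if (k %in% c("lowpass_mhz", "max_delay_s") && is.character(v) &&
        tolower(v) %in% c("inf", "infinity")) v <- Inf
    if (k == "delay_median_filter") v <- as.logical(v)
    args[[k]] <- v
  }
  do.call(new, c(list("PipelineConfig"), args))
}

#' Load a pipeline configuration from a YAML key-value file
#'
#' Keys absent from the file take the package defaults. The strings
#' \code{"inf"}/\code{"infinity"} (case-insensitive) and YAML \code{.inf} are
#' accepted for \code{lowpass_mhz} and \code{max_delay_s} to disable the
#' filter / unbound the delay search.
#'
#' @param path path to a YAML file of \code{key: value} pairs.
#' @return a \linkS4class{PipelineConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must be a YAML mapping of key: value pairs")
  do.call(pipelineConfig, vals)
}

#' @describeIn pipelineConfig coerce a configuration to a named list.
#' @param config a \linkS4class{PipelineConfig}.
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  sn <- slotNames("PipelineConfig")
  setNames(lapply(sn, function(s) slot(config, s)), sn)
}

#' @describeIn pipelineConfig md5 digest of the configuration, used to key
#'   experiment outputs to the exact pipeline that produced them.
#' @export
configDigest <- function(config) {
  l <- configAsList(config)
  txt <- paste(names(l), vapply(l, function(v) paste(format(v, digits = 17),
                                                     collapse = ","), ""),
               sep = "=", collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

setMethod("show", "PipelineConfig", function(object) {
  l <- configAsList(object)
  cat("PipelineConfig:\n")
  for (k in names(l)) cat(sprintf("  %-24s %s\n", k, paste(l[[k]], collapse = " ")))
})
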