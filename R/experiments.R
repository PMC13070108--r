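# Experiment drivers: univariate parameter sweeps, the
# detrend x low-pass x confound-threshold interaction grid, optimized
# perturbation curves, the smoothing trade-off, and the delay-alignment
# "fake steal" analysis, all on synthetic cohorts with known truth.

# fit both sessions of one synthetic subject under a configuration
.fitPair <- function(pair, config, labels = NULL, verbose = FALSE) {
  list(test = fitRun(pair$test@bold, config, etco2 = pair$test@etco2,
                     motion = pair$test@motion, labels = labels,
                     verbose = verbose),
       retest = fitRun(pair$retest@bold, config, etco2 = pair$retest@etco2,
                       motion = pair$retest@motion, labels = labels,
                       verbose = verbose))
}

# per-subject spatial ICC(C,1) for one paradigm of a cohort under a config
.cohortICC <- function(cohort, paradigm, config, verbose = FALSE) {
  subs <- cohort$subjects[[paradigm]]
  if (is.null(subs)) stop("cohort has no paradigm ", paradigm)
  digest <- configDigest(config)
  rows <- lapply(names(subs), function(sid) {
    out <- tryCatch({
      fits <- .fitPair(subs[[sid]], config,
                       labels = subs[[sid]]$test@truth@labels,
                       verbose = verbose)
      sel <- fits$test@valid & fits$retest@valid
      icc <- iccC1(fits$test@cvr[sel], fits$retest@cvr[sel])
      data.frame(subject = sid, icc = icc, fisher_z = fisherZ(icc),
                 failed = FALSE, digest = digest)
    }, error = function(e) data.frame(subject = sid, icc = NA_real_,
                                      fisher_z = NA_real_, failed = TRUE,
                                      digest = digest))
    out
  })
  do.call(rbind, rows)
}

#' Univariate parameter sweep
#'
#' Varies one configuration parameter over the given levels, holding the
#' others at the base configuration, and computes per-subject spatial
#' ICC(C,1) (with Fisher z) for each level. A level where more than 20% of
#' subjects fail is flagged.
#'
#' @param cohort a cohort from \code{\link{generateCohort}}.
#' @param paradigm which paradigm of the cohort to sweep.
#' @param parameter configuration field name, e.g. \code{"fwhm_mm"}.
#' @param levels ordered vector of parameter values (>= 1; >= 2 for a real
#'   sweep, a single level is allowed for smoke tests).
#' @param base_config base \linkS4class{PipelineConfig}.
#' @param verbose log stage messages.
#' @return data.frame with one row per level x subject: parameter, level,
#'   subject, icc, fisher_z, failed, condition_flagged, digest.
#' @export
univariateSweep <- function(cohort, paradigm, parameter, levels,
                            base_config = pipelineConfig(),
                            verbose = FALSE) {
  if (!parameter %in% slotNames("PipelineConfig"))
    stop("unknown configuration parameter: ", parameter)
  rows <- lapply(levels, function(lv) {
    cfg <- do.call(pipelineConfig,
                   modifyList(configAsList(base_config),
                              setNames(list(lv), parameter)))
    df <- .cohortICC(cohort, paradigm, cfg, verbose = verbose)
    df$parameter <- parameter
    df$level <- lv
    df$condition_flagged <- mean(df$failed) > 0.2
    df
  })
  do.call(rbind, rows)
}

#' Full-factorial interaction grid
#'
#' Evaluates every combination of detrend order, low-pass cutoff and
#' confound-correlation threshold on a cohort, returning the long-format
#' per-subject table (suitable for external repeated-measures analysis)
#' together with per-cell mean Fisher-z ICC.
#'
#' @param cohort a cohort from \code{\link{generateCohort}}.
#' @param paradigm which paradigm to evaluate.
#' @param detrend_levels,cutoff_levels,threshold_levels level vectors for the
#'   three parameters.
#' @param base_config base \linkS4class{PipelineConfig}.
#' @param verbose log stage messages.
#' @return list with \code{table} (per-subject long format) and \code{cells}
#'   (per-cell mean fisher_z and icc).
#' @export
interactionGrid <- function(cohort, paradigm, detrend_levels, cutoff_levels,
                            threshold_levels,
                            base_config = pipelineConfig(),
                            verbose = FALSE) {
  grid <- expand.grid(detrend_order = detrend_levels,
                      lowpass_mhz = cutoff_levels,
                      confound_corr_threshold = threshold_levels)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- do.call(pipelineConfig,
                   modifyList(configAsList(base_config),
                              as.list(grid[i, ])))
    df <- .cohortICC(cohort, paradigm, cfg, verbose = verbose)
    cbind(grid[i, ], df, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  cells <- aggregate(cbind(fisher_z, icc) ~ detrend_order + lowpass_mhz +
                       confound_corr_threshold, data = tab, FUN = mean,
                     na.action = stats::na.omit)
  list(table = tab, cells = cells)
}

#' Optimized perturbation curves from an interaction grid
#'
#' For each of the three grid parameters, fixes the other two at their
#' empirically optimal values (the cell with the highest mean Fisher-z ICC;
#' ties broken toward the supplied defaults) and reports the curve over its
#' levels. The global best cell is flagged on every curve.
#'
#' @param grid output of \code{\link{interactionGrid}}.
#' @param defaults named list of default parameter values used to break ties.
#' @return list with \code{best} (the optimal cell) and \code{curves}
#'   (data.frame: parameter, level, mean fisher_z, icc, is_best_cell).
#' @export
optimizedPerturbation <- function(grid,
                                  defaults = list(detrend_order = 1,
                                                  lowpass_mhz = 116.4,
                                                  confound_corr_threshold = 0)) {
  cells <- grid$cells
  pars <- c("detrend_order", "lowpass_mhz", "confound_corr_threshold")
  top <- cells[cells$fisher_z >= max(cells$fisher_z) - 1e-12, , drop = FALSE]
  if (nrow(top) > 1) {
    nDef <- rowSums(vapply(pars, function(p)
      abs(top[[p]] - defaults[[p]]) < 1e-12, logical(nrow(top))))
    top <- top[order(-nDef), , drop = FALSE]
  }
  best <- top[1, , drop = FALSE]
  curves <- do.call(rbind, lapply(pars, function(p) {
    others <- setdiff(pars, p)
    sel <- rep(TRUE, nrow(cells))
    for (o in others) sel <- sel & abs(cells[[o]] - best[[o]]) < 1e-12
    cv <- cells[sel, , drop = FALSE]
    data.frame(parameter = p, level = cv[[p]], fisher_z = cv$fisher_z,
               icc = cv$icc,
               is_best_cell = abs(cv[[p]] - best[[p]]) < 1e-12)
  }))
  list(best = best, curves = curves)
}

#' Reference-map perturbation: correlation with a designated reference
#'
#' Variant of the sweep metric replacing test--retest ICC with the voxel-wise
#' Pearson correlation of each fitted map against a reference CVR map.
#'
#' @param cohort a cohort from \code{\link{generateCohort}}.
#' @param paradigm which paradigm to evaluate.
#' @param parameter,levels parameter to vary and its levels.
#' @param reference a \linkS4class{CVRResult} whose CVR map is the reference.
#' @param base_config base \linkS4class{PipelineConfig}.
#' @return data.frame: parameter, level, subject, session, correlation.
#' @export
referenceMapSweep <- function(cohort, paradigm, parameter, levels, reference,
                              base_config = pipelineConfig()) {
  refMap <- reference@cvr
  rows <- lapply(levels, function(lv) {
    cfg <- do.call(pipelineConfig,
                   modifyList(configAsList(base_config),
                              setNames(list(lv), parameter)))
    subs <- cohort$subjects[[paradigm]]
    do.call(rbind, lapply(names(subs), function(sid) {
      fits <- .fitPair(subs[[sid]], cfg,
                       labels = subs[[sid]]$test@truth@labels)
      data.frame(parameter = parameter, level = lv, subject = sid,
                 session = c("test", "retest"),
                 correlation = c(mapCorrelation(fits$test@cvr, refMap),
                                 mapCorrelation(fits$retest@cvr, refMap)))
    }))
  })
  do.call(rbind, rows)
}

#' Fake-steal analysis of a delay-aligned test--retest pair
#'
#' Classifies common valid voxels: a voxel is \emph{anti-correlated}
#' ("fake steal") iff its CVR sign flips between sessions while the
#' amplitudes stay similar
#' (\code{||test| - |retest|| / max(|test|, |retest|) < amp_tol}); sign-stable
#' voxels are \emph{consistent}. Reports the anti-correlated fraction, the
#' histogram (2 s bins) and mode of absolute test--retest delay differences
#' per class, and the regressor--BOLD correlation distributions per class.
#'
#' @param test,retest \linkS4class{CVRResult}s fitted with delay alignment.
#' @param amp_tol amplitude-similarity tolerance (default 0.5).
#' @param bin_width_s histogram bin width in seconds (default 2).
#' @return list with \code{anti_fraction}, \code{delay_diff_mode_s} (mode of
#'   the anti-class histogram), \code{hist_anti}, \code{hist_consistent},
#'   \code{rcorr_anti}, \code{rcorr_consistent}, \code{n_common}.
#' @export
fakeStealAnalysis <- function(test, retest, amp_tol = 0.5, bin_width_s = 2) {
  sel <- test@valid & retest@valid
  if (!any(sel)) stop("no common valid voxels")
  a <- test@cvr[sel]; b <- retest@cvr[sel]
  ampSim <- abs(abs(a) - abs(b)) / pmax(abs(a), abs(b)) < amp_tol
  anti <- sign(a) != sign(b) & ampSim
  consistent <- sign(a) == sign(b)
  dd <- abs(test@delay[sel] - retest@delay[sel])
  mkHist <- function(x) {
    if (!length(x)) return(data.frame(mid_s = numeric(), count = integer()))
    brk <- seq(0, max(x, bin_width_s) + bin_width_s, by = bin_width_s)
    h <- hist(x, breaks = brk, plot = FALSE)
    data.frame(mid_s = h$mids, count = h$counts)
  }
  hAnti <- mkHist(dd[anti])
  mode_s <- if (nrow(hAnti) && any(hAnti$count > 0))
    hAnti$mid_s[which.max(hAnti$count)] else NA_real_
  rc <- cbind(test@rcorr[sel], retest@rcorr[sel])
  list(anti_fraction = mean(anti),
       delay_diff_mode_s = mode_s,
       hist_anti = hAnti,
       hist_consistent = mkHist(dd[consistent]),
       rcorr_anti = as.numeric(rc[anti, ]),
       rcorr_consistent = as.numeric(rc[consistent, ]),
       n_common = sum(sel))
}

#' Smoothing trade-off: repeatability vs subject and tissue contrast
#'
#' For each smoothing level: mean within-subject correlation, differential
#' correlation, and mean CVR in GM/WM/CSF/WB on the group-average map.
#'
#' @param cohort a cohort from \code{\link{generateCohort}}.
#' @param paradigm which paradigm to evaluate.
#' @param fwhm_levels smoothing levels in mm.
#' @param base_config base \linkS4class{PipelineConfig}.
#' @param verbose log stage messages.
#' @return data.frame: fwhm_mm, within, between, differential, gm_mean,
#'   wm_mean, csf_mean, wb_mean.
#' @export
smoothingTradeoff <- function(cohort, paradigm, fwhm_levels,
                              base_config = pipelineConfig(),
                              verbose = FALSE) {
  subs <- cohort$subjects[[paradigm]]
  labels <- subs[[1]]$test@truth@labels
  rows <- lapply(fwhm_levels, function(fw) {
    cfg <- do.call(pipelineConfig,
                   modifyList(configAsList(base_config),
                              list(fwhm_mm = fw)))
    fits <- lapply(subs, .fitPair, config = cfg, labels = labels,
                   verbose = verbose)
    vols <- unlist(lapply(fits, function(p)
      list(p$test@valid, p$retest@valid)), recursive = FALSE)
    cm <- commonValidMask(vols, 0.5)
    maps <- lapply(fits, function(p)
      list(test = p$test@cvr, retest = p$retest@cvr))
    dc <- differentialCorrelation(maps, cm)
    gavg <- Reduce(`+`, lapply(maps, function(m) {
      t1 <- m$test; t1[is.na(t1)] <- 0; t2 <- m$retest; t2[is.na(t2)] <- 0
      (t1 + t2) / 2
    })) / length(maps)
    tmean <- function(code) mean(gavg[cm & labels == code])
    data.frame(fwhm_mm = fw, within = dc$within, between = dc$between,
               differential = dc$differential,
               gm_mean = tmean(1L), wm_mean = tmean(2L),
               csf_mean = tmean(3L), wb_mean = mean(gavg[cm & labels > 0L]))
  })
  do.call(rbind, rows)
}
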