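#' Estimate the hemodynamic delay of one voxel
#'
#' Shifts the regressor over integer lags within \code{+-max_delay_s} and
#' returns the lag maximizing the absolute Pearson correlation with the BOLD
#' series on the overlapping support (at least 10 samples). Positive delay
#' means the regressor is moved later in time. Ties are broken toward the
#' smallest absolute lag, then toward positive lag. \code{max_delay_s = 0}
#' returns delay 0 with the regressor unshifted.
#'
#' @param bold single-voxel BOLD series (\linkS4class{SampledSeries}).
#' @param regressor regressor on the same sampling grid.
#' @param max_delay_s delay bound in seconds (>= 0, or \code{Inf}).
#' @return list with \code{delay_s}, \code{regressor} (shifted, edge
#'   replicated) and \code{r} (signed correlation at the chosen lag).
#' @export
estimateVoxelDelay <- function(bold, regressor, max_delay_s) {
  stopifnot(is(bold, "SampledSeries"), is(regressor, "SampledSeries"))
  if (abs(bold@dt - regressor@dt) > 1e-9)
    stop("bold and regressor must share one sampling interval")
  if (max_delay_s < 0) stop("max_delay_s must be >= 0")
  n <- min(length(bold@values), length(regressor@values))
  x <- bold@values[1:n]; y <- regressor@values[1:n]
  if (max_delay_s == 0) {
    return(list(delay_s = 0, regressor = regressor, r = cor(x, y)))
  }
  K <- if (is.finite(max_delay_s)) floor(max_delay_s / bold@dt + 1e-9) else
    n - 11L
  K <- min(K, n - 11L)
  fit <- .bestLag(x, y, K, useAbs = TRUE)
  list(delay_s = fit$lag * bold@dt,
       regressor = initialize(regressor,
                              values = .shiftSeries(regressor@values, fit$lag)),
       r = fit$r)
}

#' Fit the CVR model for one voxel
#'
#' Ordinary least squares of the PSC-scaled BOLD series on an intercept, the
#' regressor, and any confounds. Rank-deficient designs drop collinear
#' confound columns by pivoted elimination; a design in which the regressor
#' itself is eliminated marks the voxel invalid.
#'
#' @param bold_psc PSC-scaled BOLD series (\linkS4class{SampledSeries}).
#' @param regressor model regressor on the same grid.
#' @param confounds optional list of confound series.
#' @return list with \code{beta} (CVR, % per regressor unit), \code{r2},
#'   \code{tvalue} and \code{valid}.
#' @export
fitVoxel <- function(bold_psc, regressor, confounds = list()) {
  y <- bold_psc@values
  r <- regressor@values
  n <- min(length(y), length(r),
           if (length(confounds))
             min(vapply(confounds, function(s) length(s@values), 1L)) else Inf)
  X <- cbind(1, r[1:n])
  for (cf in confounds) X <- cbind(X, cf@values[1:n])
  fit <- .olsBatch(matrix(y[1:n], ncol = 1), X)
  list(beta = fit$beta[1], r2 = fit$r2[1], tvalue = fit$tvalue[1],
       valid = fit$valid[1])
}

# batched OLS of Y (time x voxels) on shared design X; regCol is the
# regressor column index
.olsBatch <- function(Y, X, regCol = 2L) {
  n <- nrow(X); V <- ncol(Y)
  out <- list(beta = rep(NA_real_, V), r2 = rep(NA_real_, V),
              tvalue = rep(NA_real_, V), valid = rep(FALSE, V))
  if (n < ncol(X) + 2L) return(out)
  q <- qr(X)
  keep <- sort(q$pivot[seq_len(q$rank)])
  if (!(regCol %in% keep)) return(out)
  Xk <- X[, keep, drop = FALSE]
  B <- qr.coef(qr(Xk), Y)
  res <- Y - Xk %*% B
  RSS <- colSums(res^2)
  TSS <- colSums(sweep(Y, 2, colMeans(Y))^2)
  dfres <- n - length(keep)
  sigma2 <- pmax(RSS, 0) / dfres
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  j <- match(regCol, keep)
  beta <- B[j, ]
  se <- sqrt(sigma2 * XtXinv[j, j])
  ok <- TSS > 0 & is.finite(beta)
  out$beta[ok] <- beta[ok]
  out$r2[ok] <- pmin(pmax(1 - RSS[ok] / TSS[ok], 0), 1)
  out$tvalue[ok] <- ifelse(se[ok] > 0, beta[ok] / se[ok], NA_real_)
  out$valid <- ok & is.finite(out$tvalue)
  out
}

# Pearson correlation of each column of Y (time x voxels) with x
.colCors <- function(Y, x) {
  n <- length(x)
  xc <- x - mean(x)
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- as.numeric(crossprod(Yc, xc))
  den <- sqrt(colSums(Yc^2) * sum(xc^2))
  ifelse(den > 0, num / den, NA_real_)
}

# vectorized delay search: P is voxels x time (trimmed fine grid), g the
# regressor on the same grid; returns per-voxel lag (samples) and signed r
.voxelDelays <- function(P, g, K, minOverlap = 10L) {
  n <- ncol(P); V <- nrow(P)
  lags <- -K:K
  lags <- lags[order(abs(lags), -sign(lags))]
  # prefix sums over time
  C1 <- matrix(0, V, n + 1L); C2 <- matrix(0, V, n + 1L)
  for (t in seq_len(n)) {
    C1[, t + 1L] <- C1[, t] + P[, t]
    C2[, t + 1L] <- C2[, t] + P[, t]^2
  }
  g1 <- c(0, cumsum(g)); g2 <- c(0, cumsum(g^2))
  bestScore <- rep(-Inf, V); bestLag <- integer(V); bestR <- rep(NA_real_, V)
  for (l in lags) {
    a <- max(1L, 1L + l); b <- min(n, n + l)
    ns <- b - a + 1L
    if (ns < minOverlap) next
    ya <- a - l; yb <- b - l
    y <- g[ya:yb]
    Sx <- C1[, b + 1L] - C1[, a]
    Sxx <- C2[, b + 1L] - C2[, a]
    Sy <- g1[yb + 1L] - g1[ya]
    Syy <- g2[yb + 1L] - g2[ya]
    Sxy <- as.numeric(P[, a:b, drop = FALSE] %*% y)
    den <- (ns * Sxx - Sx^2) * (ns * Syy - Sy^2)
    r <- ifelse(den > 0, (ns * Sxy - Sx * Sy) / sqrt(den), NA_real_)
    sc <- abs(r)
    upd <- which(!is.na(sc) & sc > bestScore + 1e-12)
    if (length(upd)) {
      bestScore[upd] <- sc[upd]; bestLag[upd] <- l; bestR[upd] <- r[upd]
    }
  }
  list(lag = bestLag, r = bestR)
}

# condition a series vector sampled at dt onto the fine grid used by fitRun:
# linear upsample to times tFine, then detrend/low-pass
.conditionVector <- function(v, dt, tFine, order, lowpass_mhz, fdt) {
  t <- (seq_along(v) - 1L) * dt
  u <- approx(t, v, xout = tFine, rule = 2)$y
  if (order > 0) {
    Q <- .polyBasisQ(length(u), order)
    u <- as.numeric(u - Q %*% crossprod(Q, u))
  }
  if (is.finite(lowpass_mhz)) {
    co <- .lowpassCoefs(lowpass_mhz, fdt, 5L)
    u <- .filtfiltMat(co$b, co$a, matrix(u, ncol = 1))[, 1]
  }
  u
}

#' Fit a full CVR run
#'
#' Runs the complete voxel-wise estimation chain on one BOLD run:
#' mask, spatial smoothing, temporal upsampling, polynomial detrending,
#' zero-phase low-pass filtering, PSC scaling, regressor preparation
#' (ET-CO2 baseline subtraction and alignment to the global signal, or the
#' global signal itself), initial trim, optional voxel-wise bounded delay
#' alignment on the upsampled grid, downsampling back to the acquisition
#' rate, motion-confound screening, OLS, and map refinement (optional delay
#' median filter with re-fit, MAD outlier filter, optional quality-quantile
#' filter and tissue normalization).
#'
#' @param run a \linkS4class{BoldRun}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param etco2 ET-CO2 trace (\linkS4class{SampledSeries}, typically 1 Hz);
#'   required when \code{regressor_kind} is "etco2".
#' @param motion list of 6 motion series at the BOLD rate; required when
#'   \code{confound_corr_threshold > 0}.
#' @param mask optional \linkS4class{BrainMask} (required when
#'   \code{mask_kind} is "provided").
#' @param labels optional 3-D tissue-label array (0 background, 1 GM, 2 WM,
#'   3 CSF) for normalization / tissue restriction.
#' @param quality_volume optional 3-D covariate (e.g. fieldmap magnitude)
#'   for the "fmap" quality metric.
#' @param verbose log stage messages to stderr.
#' @return a \linkS4class{CVRResult}.
#' @export
fitRun <- function(run, config, etco2 = NULL, motion = NULL, mask = NULL,
                   labels = NULL, quality_volume = NULL, verbose = FALSE) {
  stopifnot(is(run, "BoldRun"), is(config, "PipelineConfig"))
  runID <- paste(run@subjectID, run@paradigm, run@session, sep = "/")
  say <- function(...) if (verbose) .log(runID, ...)

  if (config@mask_kind == "epi") mask <- makeEpiMask(run)
  else if (is.null(mask)) stop("mask_kind 'provided' requires a mask")
  maskArr <- mask@mask
  if (config@tissue_restrict != "WB") {
    if (is.null(labels)) stop("tissue_restrict requires a label volume")
    code <- c(GM = 1L, WM = 2L, CSF = 3L)[config@tissue_restrict]
    maskArr <- maskArr & (labels == code)
    if (!any(maskArr)) stop("tissue-restricted mask is empty")
  }
  maskIdx <- which(maskArr)
  d <- dim(run@data)
  nt <- d[4]
  Vraw <- matrix(run@data, prod(d[1:3]), nt)[maskIdx, , drop = FALSE]

  gsRaw <- colSums(matrix(run@data, prod(d[1:3]), nt)[which(mask@mask), ,
                                                      drop = FALSE])
  say("mask: ", length(maskIdx), " voxels")

  sm <- gaussianSmooth(run, config@fwhm_mm)
  V <- matrix(sm@data, prod(d[1:3]), nt)[maskIdx, , drop = FALSE]

  # temporal upsampling onto the fine grid
  u <- config@upsample_factor
  fdt <- run@dt / u
  ntu <- (nt - 1L) * u + 1L
  tFine <- (seq_len(ntu) - 1L) * fdt
  pos <- tFine / run@dt
  i0 <- pmin(floor(pos) + 1L, nt - 1L)
  frac <- pos - (i0 - 1L)
  Vu <- V[, i0, drop = FALSE] * matrix(1 - frac, nrow(V), ntu, byrow = TRUE) +
    V[, i0 + 1L, drop = FALSE] * matrix(frac, nrow(V), ntu, byrow = TRUE)

  # PSC baseline from the acquisition-rate frames (mean of the raw series)
  tFrame <- (seq_len(nt) - 1L) * run@dt
  baseline <- if (config@baseline_strategy == "overall_mean") rowMeans(V)
    else rowMeans(V[, tFrame < config@trim_initial_s, drop = FALSE])

  if (config@detrend_order > 0) {
    Q <- .polyBasisQ(ntu, config@detrend_order)
    Vu <- Vu - (Vu %*% Q) %*% t(Q)
  }
  if (is.finite(config@lowpass_mhz)) {
    co <- .lowpassCoefs(config@lowpass_mhz, fdt, 5L)
    Vu <- t(.filtfiltMat(co$b, co$a, t(Vu)))
    say("low-pass at ", config@lowpass_mhz, " mHz")
  }
  okBase <- is.finite(baseline) & baseline > 0
  P <- 100 * (Vu - rowMeans(Vu)) / ifelse(okBase, baseline, NA_real_)

  gsCond <- .conditionVector(gsRaw, run@dt, tFine, config@detrend_order,
                             config@lowpass_mhz, fdt)
  gsPsc <- 100 * (gsCond - mean(gsCond)) / mean(gsRaw)

  if (config@regressor_kind == "etco2") {
    if (is.null(etco2)) stop("regressor_kind 'etco2' requires an etco2 series")
    et <- .conditionVector(etco2@values, etco2@dt, tFine,
                           config@detrend_order, config@lowpass_mhz, fdt)
    et <- et - mean(et)
    K15 <- floor(15 / fdt + 1e-9)
    al <- .bestLag(gsPsc, et, K15, useAbs = FALSE)
    if (al$atBound) say("ET-CO2 alignment clipped at +-15 s")
    g <- .shiftSeries(et, al$lag)
    regShift <- al$lag * fdt
    say(sprintf("ET-CO2 aligned to global signal: shift %.3g s", regShift))
  } else {
    g <- gsPsc
    regShift <- 0
  }

  # initial trim, applied to every model series; the first kept sample is
  # aligned to the acquisition grid so that downsampling recovers original
  # frame times rather than interpolated midpoints
  firstKeep <- which(tFine >= config@trim_initial_s - 1e-9)[1]
  if (is.na(firstKeep)) stop("trim_initial_s leaves no samples")
  firstKeep <- firstKeep + (u - (firstKeep - 1L) %% u) %% u
  keepT <- seq_len(ntu) >= firstKeep
  P <- P[, keepT, drop = FALSE]
  g <- g[keepT]
  nTrim <- sum(keepT)
  if (sd(g) == 0) stop("regressor is constant after conditioning")

  # confounds: expand, condition like every other series, screen
  confFine <- NULL
  if (config@confound_corr_threshold > 0) {
    if (is.null(motion)) stop("confound screening requires motion series")
    conf24 <- expandMotionConfounds(motion)
    confFine <- vapply(conf24, function(s)
      .conditionVector(s@values, s@dt, tFine, config@detrend_order,
                       config@lowpass_mhz, fdt)[keepT], numeric(nTrim))
  }

  dIdx <- seq(1L, nTrim, by = u)   # back to the acquisition rate
  gDown <- g[dIdx]
  confKeep <- NULL
  if (!is.null(confFine)) {
    confDown <- confFine[dIdx, , drop = FALSE]
    keepC <- vapply(seq_len(ncol(confDown)), function(j) {
      v <- confDown[, j]
      sd(v) > 0 && abs(cor(v, gDown)) < config@confound_corr_threshold
    }, TRUE)
    confKeep <- confDown[, keepC, drop = FALSE]
    say("confounds retained: ", sum(keepC), "/24")
  }

  nv <- length(maskIdx)
  res <- .fitWithLags(P, g, confKeep, u, fdt, config, nv, okBase, say)

  if (config@delay_median_filter && config@max_delay_s > 0) {
    sh <- d[1:3]
    delayArr <- array(NA_real_, sh); delayArr[maskIdx] <- res$delay
    validArr <- array(FALSE, sh); validArr[maskIdx] <- res$valid
    filt <- medianFilterDelays(delayArr, validArr)
    fixedLag <- as.integer(round(filt[maskIdx] / fdt))
    say("delay median filter applied; re-fitting")
    res <- .fitWithLags(P, g, confKeep, u, fdt, config, nv, okBase, say,
                        fixedLag = fixedLag)
  }

  valid <- res$valid
  valid <- madOutlierFilter(res$beta, valid, config@mad_z_threshold,
                            logFun = say)

  if (config@quality_metric != "none") {
    metric <- switch(config@quality_metric,
      r2 = res$r2,
      tvalue = res$tvalue,
      tsnr = {
        mu <- rowMeans(Vraw); sdv <- apply(Vraw, 1, sd)
        ifelse(sdv > 0, mu / sdv, NA_real_)
      },
      fmap = {
        if (is.null(quality_volume))
          stop("quality_metric 'fmap' requires a quality_volume")
        quality_volume[maskIdx]
      })
    valid <- qualityQuantileFilter(valid, metric, config@quality_quantile)
    say("quality filter (", config@quality_metric, "): ",
        sum(valid), " voxels retained")
  }

  sh <- d[1:3]
  mkMap <- function(v) {
    a <- array(NA_real_, sh)
    a[maskIdx] <- v
    a[maskIdx][!valid] <- NA_real_
    a
  }
  cvrA <- array(NA_real_, sh); cvrA[maskIdx] <- ifelse(valid, res$beta, NA_real_)
  delayA <- array(NA_real_, sh); delayA[maskIdx] <- ifelse(valid, res$delay, NA_real_)
  r2A <- array(NA_real_, sh); r2A[maskIdx] <- ifelse(valid, res$r2, NA_real_)
  tA <- array(NA_real_, sh); tA[maskIdx] <- ifelse(valid, res$tvalue, NA_real_)
  rcA <- array(NA_real_, sh); rcA[maskIdx] <- ifelse(valid, res$rcorr, NA_real_)
  vA <- array(FALSE, sh); vA[maskIdx] <- valid
  if (!any(vA)) stop("all voxels invalid for run ", runID)

  result <- new("CVRResult", cvr = cvrA, delay = delayA, r2 = r2A,
                tvalue = tA, rcorr = rcA, valid = vA, grid = run@grid,
                paradigm = run@paradigm, session = run@session,
                subjectID = run@subjectID,
                regressorKind = config@regressor_kind,
                regressorShift = regShift,
                configDigest = configDigest(config))
  if (config@normalization != "none")
    result <- normalizeMap(result, config@normalization, labels)
  result
}

# delay search (or fixed lags) + per-lag-group batched OLS
.fitWithLags <- function(P, g, confKeep, u, fdt, config, nv, okBase, say,
                         fixedLag = NULL) {
  nTrim <- ncol(P)
  beta <- rep(NA_real_, nv); r2 <- rep(NA_real_, nv)
  tval <- rep(NA_real_, nv); rcor <- rep(NA_real_, nv)
  delay <- rep(0, nv)
  dIdx <- seq(1L, nTrim, by = u)
  Pok <- P; Pok[!okBase, ] <- 0   # keep matrix math finite; flagged invalid later

  if (!is.null(fixedLag)) {
    lagVox <- fixedLag
    lagVox[is.na(lagVox)] <- 0L
  } else if (config@max_delay_s > 0) {
    K <- if (is.finite(config@max_delay_s))
      floor(config@max_delay_s / fdt + 1e-9) else nTrim - 11L
    K <- min(K, nTrim - 11L)
    dl <- .voxelDelays(Pok, g, K)
    lagVox <- dl$lag
    say("delay search over +-", K, " fine-grid lags")
  } else {
    lagVox <- integer(nv)
  }

  for (l in unique(lagVox)) {
    vox <- which(lagVox == l)
    a <- max(1L, 1L + l); b <- min(nTrim, nTrim + l)
    rows <- dIdx[dIdx >= a & dIdx <= b]
    if (length(rows) < 12L) next
    x <- g[rows - l]
    X <- cbind(1, x)
    if (!is.null(confKeep) && ncol(confKeep) > 0) {
      # confounds live on the downsampled grid indexed by dIdx
      X <- cbind(X, confKeep[match(rows, dIdx), , drop = FALSE])
    }
    Y <- t(Pok[vox, rows, drop = FALSE])
    fit <- .olsBatch(Y, X)
    beta[vox] <- fit$beta; r2[vox] <- fit$r2; tval[vox] <- fit$tvalue
    rcor[vox] <- .colCors(Y, x)
    delay[vox] <- l * fdt
    okFit <- fit$valid
    beta[vox][!okFit] <- NA_real_
  }
  valid <- okBase & is.finite(beta)
  list(beta = beta, r2 = r2, tvalue = tval, rcorr = rcor, delay = delay,
       valid = valid)
}

#' MAD outlier filter on a CVR map
#'
#' Modified z-score \code{(x - median) / (1.4826 * MAD)}; voxels with
#' \code{|z|} above the threshold are invalidated (threshold 10 is
#' approximately a 10-standard-deviation exclusion under normality). A zero
#' MAD is degenerate: nothing is excluded.
#'
#' @param values numeric vector or 3-D map of CVR estimates.
#' @param valid logical vector/array of currently valid entries.
#' @param z_threshold positive modified-z threshold (default 10).
#' @param logFun optional logger taking message parts.
#' @return updated logical validity, same shape as \code{valid}.
#' @export
madOutlierFilter <- function(values, valid, z_threshold = 10,
                             logFun = NULL) {
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  v <- values[valid]
  if (length(v) < 10L) return(valid)
  med <- median(v)
  madRaw <- median(abs(v - med))
  if (madRaw == 0) {
    if (!is.null(logFun)) logFun("MAD = 0 (degenerate); no outliers excluded")
    return(valid)
  }
  z <- (values - med) / (1.4826 * madRaw)
  out <- valid
  out[valid & abs(z) > z_threshold] <- FALSE
  if (!is.null(logFun))
    logFun("MAD filter excluded ", sum(valid) - sum(out), " voxels")
  out
}

#' Quality-quantile filter
#'
#' Invalidates currently valid voxels whose quality metric falls strictly
#' below the q-quantile of the valid-voxel metric values; ties at the
#' threshold are kept.
#'
#' @param valid logical vector/array of valid voxels.
#' @param metric numeric vector/array of quality values, aligned with
#'   \code{valid}.
#' @param q quantile in (0, 1); the lowest fraction q is removed.
#' @return updated logical validity.
#' @export
qualityQuantileFilter <- function(valid, metric, q) {
  if (q <= 0 || q >= 1) stop("q must lie in (0,1)")
  vals <- metric[valid]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(valid)
  thr <- quantile(vals, q, names = FALSE)
  out <- valid
  out[valid & (!is.finite(metric) | metric < thr)] <- FALSE
  out
}

#' Temporal signal-to-noise ratio map
#'
#' Per-voxel temporal mean divided by temporal SD, computed on raw BOLD
#' data. Constant voxels are invalid (NA).
#'
#' @param run a \linkS4class{BoldRun} with at least 3 frames.
#' @return 3-D numeric array.
#' @export
tsnrMap <- function(run) {
  stopifnot(is(run, "BoldRun"))
  d <- dim(run@data)
  if (d[4] < 3) stop("tSNR needs at least 3 frames")
  M <- matrix(run@data, prod(d[1:3]), d[4])
  mu <- rowMeans(M)
  sdv <- sqrt(pmax(rowMeans(M^2) - mu^2, 0) * d[4] / (d[4] - 1))
  array(ifelse(sdv > 0, mu / sdv, NA_real_), d[1:3])
}

#' Normalize a CVR map to a tissue reference mean
#'
#' Divides the CVR map by the mean CVR over the reference tissue's valid
#' voxels (GM, WM, CSF, or the whole brain).
#'
#' @param result a \linkS4class{CVRResult}.
#' @param reference "GM", "WM", "CSF" or "WB".
#' @param labels 3-D tissue-label array (required unless reference = "WB").
#' @return the normalized \linkS4class{CVRResult}.
#' @export
normalizeMap <- function(result, reference, labels = NULL) {
  stopifnot(is(result, "CVRResult"))
  reference <- match.arg(reference, c("WB", "GM", "WM", "CSF"))
  sel <- result@valid
  if (reference != "WB") {
    if (is.null(labels)) stop("tissue normalization requires a label volume")
    code <- c(GM = 1L, WM = 2L, CSF = 3L)[reference]
    sel <- sel & (labels == code)
  }
  if (!any(sel)) stop("reference tissue has no valid voxels")
  m <- mean(result@cvr[sel])
  if (abs(m) < 1e-12) stop("reference mean CVR is within 1e-12 of zero")
  initialize(result, cvr = result@cvr / m)
}

#' 3x3x3 median filter on a delay map
#'
#' Per-voxel median of the delay over the 3x3x3 neighborhood intersected
#' with the valid voxels; boundary neighborhoods shrink. Invalid voxels are
#' left unchanged. Applied before a CVR re-fit to suppress isolated delay
#' outliers ("fake steal" voxels).
#'
#' @param delay 3-D numeric delay map (s).
#' @param valid 3-D logical validity map.
#' @return filtered 3-D delay map.
#' @export
medianFilterDelays <- function(delay, valid) {
  d <- dim(delay)
  vals <- delay
  vals[!valid] <- NA_real_
  neigh <- matrix(NA_real_, length(delay), 27L)
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy; zs <- seq_len(d[3]) + dz
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    src <- array(NA_real_, d)
    src[okx, oky, okz] <- vals[xs[okx], ys[oky], zs[okz]]
    neigh[, k] <- src
  }
  med <- apply(neigh, 1, median, na.rm = TRUE)
  out <- delay
  idx <- which(valid)
  out[idx] <- ifelse(is.nan(med[idx]) | is.na(med[idx]), delay[idx], med[idx])
  out
}

#' Voxels valid in a minimum fraction of runs
#'
#' @param validities list of 3-D logical arrays (one per subject x run).
#' @param min_frac minimum fraction in (0, 1]; a voxel is kept iff valid in
#'   at least that fraction of volumes (inclusive).
#' @return 3-D logical array.
#' @export
commonValidMask <- function(validities, min_frac = 0.5) {
  if (!length(validities)) stop("need at least one validity volume")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0,1]")
  s <- Reduce(`+`, lapply(validities, function(v) v * 1L))
  s >= min_frac * length(validities) - 1e-12
}
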