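#' Compute a brain mask from EPI intensities
#'
#' Heuristic EPI mask: voxels whose temporal-mean intensity exceeds the 2nd
#' percentile plus 20% of the 2nd--98th percentile span are included, then
#' only the largest 6-connected component is kept.
#'
#' @param run a \linkS4class{BoldRun} with at least 2 frames.
#' @return a \linkS4class{BrainMask} of kind "epi".
#' @export
makeEpiMask <- function(run) {
  stopifnot(is(run, "BoldRun"))
  m <- rowMeans(matrix(run@data, prod(dim(run@data)[1:3]), dim(run@data)[4]))
  p <- quantile(m, c(0.02, 0.98), names = FALSE)
  thr <- p[1] + 0.2 * (p[2] - p[1])
  inc <- array(m > thr, dim(run@data)[1:3])
  if (!any(inc)) stop("EPI mask is empty: no voxels above intensity threshold")
  keep <- .largestComponent(inc)
  BrainMask(keep, grid = run@grid, kind = "epi")
}

# largest 6-connected component of a 3-D logical array (BFS over flat indices)
.largestComponent <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  idx <- which(m)
  nxt <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  coord <- arrayInd(idx, d)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  sizes <- integer(0)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt; count <- 0L
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      count <- count + 1L
      ci <- coord[pos[v], ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        cj <- ci[ax] + s
        if (cj < 1L || cj > d[ax]) next
        w <- v + s * strides[ax]
        if (m[w] && lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
    sizes[nxt] <- count
  }
  lab == which.max(sizes)
}

#' Spatial Gaussian smoothing of a 4-D run
#'
#' Per-frame separable 3-D Gaussian convolution. The kernel width is given as
#' full width at half maximum in millimetres and converted to a per-axis sigma
#' in voxels, \code{sigma_vox = fwhm / (2 sqrt(2 ln 2)) / voxel_mm}. Edges use
#' nearest-value replication, so constant volumes are preserved exactly and
#' kernel mass is conserved. \code{fwhm_mm = 0} returns the input unchanged.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param fwhm_mm kernel FWHM in mm, >= 0.
#' @return a smoothed \linkS4class{BoldRun}.
#' @export
gaussianSmooth <- function(run, fwhm_mm) {
  stopifnot(is(run, "BoldRun"))
  if (length(fwhm_mm) != 1 || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single real >= 0")
  if (fwhm_mm == 0) return(run)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / run@grid@voxelSize
  a <- run@data
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    S <- .gaussSmootherMatrix(dim(a)[ax], sig[ax])
    a <- .applyAlongAxis(a, ax, S)
  }
  initialize(run, data = a)
}

# L x L smoothing matrix with replicate-edge handling
.gaussSmootherMatrix <- function(L, sigma) {
  R <- max(1L, ceiling(4 * sigma))
  off <- -R:R
  k <- exp(-0.5 * (off / sigma)^2)
  k <- k / sum(k)
  S <- matrix(0, L, L)
  for (i in seq_len(L)) {
    j <- pmin(pmax(i + off, 1L), L)   # clamp: out-of-range mass to the edge
    for (m in seq_along(j)) S[i, j[m]] <- S[i, j[m]] + k[m]
  }
  S
}

.applyAlongAxis <- function(a, ax, S) {
  d <- dim(a)
  perm <- c(ax, setdiff(seq_along(d), ax))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- S %*% matrix(ap, dp[1], prod(dp[-1]))
  aperm(array(m, dp), order(perm))
}

#' Resample a series by linear interpolation
#'
#' Either upsample by an integer factor (new dt = dt/factor, endpoints
#' preserved, factor 1 is the identity) or interpolate onto a uniform grid
#' with a target sampling interval.
#'
#' @param s a \linkS4class{SampledSeries}.
#' @param factor integer upsampling factor 1--4.
#' @param target_dt target sampling interval in seconds.
#' @return a resampled \linkS4class{SampledSeries}.
#' @export
resampleSeries <- function(s, factor = NULL, target_dt = NULL) {
  stopifnot(is(s, "SampledSeries"))
  if (is.null(factor) == is.null(target_dt))
    stop("supply exactly one of factor or target_dt")
  t <- seriesTimes(s)
  if (!is.null(factor)) {
    if (factor != round(factor) || factor < 1 || factor > 4)
      stop("factor must be an integer in 1..4")
    if (factor == 1) return(s)
    newdt <- s@dt / factor
    xout <- s@t0 + (seq_len((length(s@values) - 1L) * factor + 1L) - 1L) * newdt
  } else {
    if (target_dt <= 0) stop("target_dt must be > 0")
    dur <- t[length(t)] - t[1]
    if (target_dt > dur)
      stop("target_dt longer than the series duration")
    newdt <- target_dt
    xout <- seq(s@t0, t[length(t)], by = newdt)
  }
  v <- approx(t, s@values, xout = xout, rule = 2)$y
  SampledSeries(v, dt = newdt, t0 = xout[1], label = s@label)
}

#' Remove a least-squares polynomial trend
#'
#' Order 0 is the identity (no detrending); order d >= 1 subtracts the
#' least-squares polynomial of degree d (intercept included).
#'
#' @param s a \linkS4class{SampledSeries}.
#' @param order integer 0--3.
#' @return detrended \linkS4class{SampledSeries}.
#' @export
polynomialDetrend <- function(s, order) {
  stopifnot(is(s, "SampledSeries"))
  if (order != round(order) || order < 0 || order > 3)
    stop("order must be an integer in 0..3")
  if (order == 0) return(s)
  n <- length(s@values)
  if (n < order + 2) stop("series shorter than order + 2 samples")
  Q <- .polyBasisQ(n, order)
  v <- s@values - Q %*% crossprod(Q, s@values)
  initialize(s, values = as.numeric(v))
}

# orthonormal polynomial basis (degrees 0..order) for n uniform samples
.polyBasisQ <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  B <- outer(x, 0:order, "^")
  qr.Q(qr(B))
}

#' Zero-phase low-pass filter
#'
#' Order-5 Butterworth-type recursive filter applied forward and backward
#' (zero phase, DC gain 1). A cutoff of \code{Inf} disables the filter; a
#' cutoff at or above the Nyquist frequency is an error instructing use of
#' \code{Inf}.
#'
#' @param s a \linkS4class{SampledSeries}.
#' @param cutoff_mhz cutoff frequency in millihertz, or \code{Inf}.
#' @param order filter order (default 5).
#' @return filtered \linkS4class{SampledSeries}.
#' @export
lowpassFilter <- function(s, cutoff_mhz, order = 5L) {
  stopifnot(is(s, "SampledSeries"))
  if (length(cutoff_mhz) != 1 || is.na(cutoff_mhz) || cutoff_mhz <= 0)
    stop("cutoff_mhz must be a positive real or Inf")
  if (!is.finite(cutoff_mhz)) return(s)
  co <- .lowpassCoefs(cutoff_mhz, s@dt, order)
  v <- .filtfiltMat(co$b, co$a, matrix(s@values, ncol = 1))[, 1]
  initialize(s, values = v)
}

#' Percent signal change scaling
#'
#' \code{100 * (s - baseline) / baseline}. The baseline is the overall series
#' mean (default) or the mean over the first \code{trim_initial_s} seconds.
#' A non-positive baseline flags the series invalid (all-NA values) rather
#' than raising an error; map assembly excludes such voxels.
#'
#' @param s a \linkS4class{SampledSeries}.
#' @param strategy "overall_mean" or "initial_window".
#' @param trim_initial_s window length for the initial-window strategy (s).
#' @return PSC-scaled \linkS4class{SampledSeries}; all-NA when invalid.
#' @export
pscScale <- function(s, strategy = "overall_mean", trim_initial_s = 15) {
  stopifnot(is(s, "SampledSeries"))
  strategy <- match.arg(strategy, c("overall_mean", "initial_window"))
  b <- if (strategy == "overall_mean") mean(s@values)
       else mean(s@values[seriesTimes(s) < s@t0 + trim_initial_s])
  if (!is.finite(b) || b <= 0)
    return(initialize(s, values = rep(NA_real_, length(s@values))))
  initialize(s, values = 100 * (s@values - b) / b)
}

#' Global signal of a run
#'
#' Sum of the raw (unscaled) voxel series inside the mask, then PSC-scaled
#' with the overall-mean baseline.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param mask a \linkS4class{BrainMask}.
#' @return the global signal as a \linkS4class{SampledSeries} in % units.
#' @export
globalSignal <- function(run, mask) {
  stopifnot(is(run, "BoldRun"), is(mask, "BrainMask"))
  if (!any(mask@mask)) stop("mask is empty")
  nvox <- prod(dim(run@data)[1:3])
  V <- matrix(run@data, nvox, dim(run@data)[4])
  gs <- colSums(V[as.vector(mask@mask), , drop = FALSE])
  pscScale(SampledSeries(gs, dt = run@dt, t0 = 0, label = "global_signal"))
}

# best lag aligning y to x: maximizes (|)pearson(x[i], y[i - l])(|) over
# integer lags |l| <= K; ties broken toward smallest |l|, then positive lag
.bestLag <- function(x, y, K, useAbs = FALSE, minOverlap = 10L) {
  lags <- -K:K
  r <- rep(NA_real_, length(lags))
  n <- length(x)
  for (j in seq_along(lags)) {
    l <- lags[j]
    xi <- max(1L, 1L + l):min(n, n + l)
    yi <- xi - l
    if (length(xi) < minOverlap) next
    sx <- sd(x[xi]); sy <- sd(y[yi])
    if (sx == 0 || sy == 0) next
    r[j] <- cor(x[xi], y[yi])
  }
  if (all(is.na(r))) stop("no admissible lag (series too short or constant)")
  score <- if (useAbs) abs(r) else r
  best <- max(score, na.rm = TRUE)
  cand <- which(!is.na(score) & score >= best - 1e-12)
  cand <- cand[order(abs(lags[cand]), -sign(lags[cand]))]
  j <- cand[1]
  list(lag = lags[j], r = r[j],
       atBound = abs(lags[j]) == K && K > 0)
}

#' Prepare the end-tidal CO2 regressor
#'
#' Subtracts the overall-mean baseline from the ET-CO2 series and aligns it
#' to the global signal by cross-correlation within +-\code{max_shift_s}
#' (acquisition-delay correction). Both series must share one sampling
#' interval. The returned series is index-shifted on the same time base with
#' edge replication; a shift hitting the bound is reported and flagged.
#'
#' @param etco2 baseline ET-CO2 series (\linkS4class{SampledSeries}).
#' @param gs global signal on the same grid.
#' @param max_shift_s alignment bound in seconds (default 15).
#' @param runID identifier used in log messages.
#' @return list with \code{series} (aligned, baseline-subtracted), \code{shift_s}
#'   (positive = ET-CO2 moved later), \code{r} (correlation at the chosen lag)
#'   and \code{clipped} (TRUE when the shift hit the bound).
#' @export
prepareEtco2 <- function(etco2, gs, max_shift_s = 15, runID = "run") {
  stopifnot(is(etco2, "SampledSeries"), is(gs, "SampledSeries"))
  if (abs(etco2@dt - gs@dt) > 1e-9)
    stop("etco2 and global signal must share one sampling interval; resample first")
  if (sd(etco2@values) == 0)
    stop("ET-CO2 series is constant: no alignment possible")
  v <- etco2@values - mean(etco2@values)
  n <- min(length(v), length(gs@values))
  K <- floor(max_shift_s / etco2@dt + 1e-9)
  fit <- .bestLag(gs@values[1:n], v[1:n], K, useAbs = FALSE)
  if (fit$atBound)
    .log(runID, sprintf("ET-CO2 alignment clipped at +-%g s bound", max_shift_s))
  shifted <- .shiftSeries(v, fit$lag)
  list(series = initialize(etco2, values = shifted),
       shift_s = fit$lag * etco2@dt, r = fit$r, clipped = fit$atBound)
}

# shift values later by l samples (l may be negative), replicating edges
.shiftSeries <- function(v, l) {
  n <- length(v)
  idx <- pmin(pmax(seq_len(n) - l, 1L), n)
  v[idx]
}

#' Interpolate sparse breath-by-breath ET-CO2 samples
#'
#' Linear interpolation between valid timestamped samples onto a uniform
#' 1 Hz base (breath-hold gaps become strictly linear ramps); leading and
#' trailing gaps hold the nearest value.
#'
#' @param times sample times in seconds.
#' @param values sampled ET-CO2 (mmHg); NA marks invalid samples.
#' @param dt output sampling interval (default 1 s).
#' @return a \linkS4class{SampledSeries}.
#' @export
interpolateSparseEtco2 <- function(times, values, dt = 1) {
  ok <- is.finite(times) & is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 valid ET-CO2 samples")
  t <- times[ok]; v <- values[ok]
  xout <- seq(min(t), max(t), by = dt)
  y <- approx(t, v, xout = xout, rule = 2)$y
  SampledSeries(y, dt = dt, t0 = xout[1], label = "etco2")
}

#' Framewise displacement from motion parameters
#'
#' \code{FD(t) = sum |delta translation| + 50 mm * sum |delta rotation|}
#' (small-angle convention with a 50 mm head radius); the first frame is 0.
#'
#' @param motion list of 6 \linkS4class{SampledSeries}: 3 translations (mm)
#'   then 3 rotations (rad), equal length.
#' @return FD as a \linkS4class{SampledSeries} in mm.
#' @export
framewiseDisplacement <- function(motion) {
  if (length(motion) != 6L) stop("motion must hold exactly 6 series")
  n <- vapply(motion, function(s) length(s@values), 1L)
  if (length(unique(n)) != 1L) stop("motion series have unequal lengths")
  M <- vapply(motion, seriesValues, numeric(n[1]))
  d <- abs(apply(M, 2, function(col) c(0, diff(col))))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE])
  SampledSeries(fd, dt = motion[[1]]@dt, t0 = motion[[1]]@t0, label = "fd")
}
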