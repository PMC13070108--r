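#' Spatial ICC(C,1): consistency intraclass correlation, single measurement
#'
#' Two-way model with voxels as targets and the two sessions as
#' measurements, with session (column) effects removed:
#' \code{ICC = (MS_target - MS_error) / (MS_target + (k-1) MS_error)}.
#' Consistency ICC ignores constant session offsets and common affine
#' rescaling.
#'
#' @param a,b aligned valid-voxel value vectors from the two sessions
#'   (length >= 3, NA pairs dropped).
#' @return ICC(C,1) in [-1, 1]; NA when target variance is zero.
#' @export
iccC1 <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 common valid voxels")
  k <- 2
  X <- cbind(a, b)
  grand <- mean(X)
  rowM <- rowMeans(X)
  colM <- colMeans(X)
  ssRow <- k * sum((rowM - grand)^2)
  ssCol <- n * sum((colM - grand)^2)
  ssTot <- sum((X - grand)^2)
  ssErr <- ssTot - ssRow - ssCol
  msRow <- ssRow / (n - 1)
  msErr <- ssErr / ((n - 1) * (k - 1))
  if (msRow + (k - 1) * msErr == 0) return(NA_real_)
  (msRow - msErr) / (msRow + (k - 1) * msErr)
}

#' Fisher z-transform of a correlation
#'
#' \code{atanh(r)}; values at or beyond +-1 are clamped to magnitude
#' \code{1 - 1e-12} with a warning.
#'
#' @param r correlation-scale value(s).
#' @return z value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clamped to 1 - 1e-12 before Fisher z")
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  }
  atanh(r)
}

#' Pearson correlation of two maps over a common mask
#'
#' @param a,b 3-D maps.
#' @param common_mask logical array of voxels to compare; defaults to voxels
#'   finite in both maps.
#' @return Pearson r.
#' @export
mapCorrelation <- function(a, b, common_mask = NULL) {
  if (is.null(common_mask)) common_mask <- is.finite(a) & is.finite(b)
  x <- a[common_mask]; y <- b[common_mask]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 common voxels")
  cor(x[ok], y[ok])
}

#' Within-, between-subject and differential map correlation
#'
#' Within = mean over subjects of the test--retest correlation of their own
#' maps; between = mean over all ordered cross-subject run pairs (all four
#' session combinations per subject pair); differential = within - between,
#' an index of how uniquely maps identify individual subjects.
#'
#' @param maps list per subject of \code{list(test = , retest = )} 3-D maps.
#' @param common_mask optional logical array restricting the comparison.
#' @return list with \code{within}, \code{between}, \code{differential} and
#'   the per-subject within correlations.
#' @export
differentialCorrelation <- function(maps, common_mask = NULL) {
  nS <- length(maps)
  if (nS < 2) stop("need at least 2 subjects")
  within <- vapply(maps, function(m)
    mapCorrelation(m$test, m$retest, common_mask), 1)
  between <- c()
  for (i in seq_len(nS)) for (j in seq_len(nS)) {
    if (i == j) next
    for (si in c("test", "retest")) for (sj in c("test", "retest"))
      between <- c(between,
                   mapCorrelation(maps[[i]][[si]], maps[[j]][[sj]],
                                  common_mask))
  }
  w <- mean(within); b <- mean(between)
  list(within = w, between = b, differential = w - b,
       perSubjectWithin = within)
}

#' Coefficient-of-variation map across runs
#'
#' Per voxel, sample SD across runs divided by the absolute mean, capped at
#' 1 (avoids arbitrarily large values when the mean CVR is near 0); a zero
#' mean gives 1.
#'
#' @param maps list of >= 2 aligned 3-D maps.
#' @return 3-D COV map in [0, 1] (NA where any run is NA).
#' @export
covMap <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 runs")
  A <- matrix(unlist(lapply(maps, as.vector)), length(maps[[1]]),
              length(maps))
  mu <- rowMeans(A)
  s <- apply(A, 1, sd)
  v <- ifelse(abs(mu) > 0, pmin(s / abs(mu), 1), 1)
  v[!is.finite(rowSums(A))] <- NA_real_
  array(v, dim(maps[[1]]))
}

#' Median-scaled absolute test--retest difference map
#'
#' \code{|test - retest| / cohort_median} per voxel, averaged across
#' subjects; the scaling median is the median CVR across voxels, subjects
#' and runs.
#'
#' @param pairs list per subject of \code{list(test = , retest = )} maps.
#' @param cohort_median scaling constant; computed from the supplied maps
#'   when NULL.
#' @return 3-D map (NA where no subject contributes).
#' @export
scaledAbsDiffMap <- function(pairs, cohort_median = NULL) {
  if (is.null(cohort_median)) {
    allv <- unlist(lapply(pairs, function(p) c(p$test, p$retest)))
    cohort_median <- median(allv, na.rm = TRUE)
  }
  if (!is.finite(cohort_median) || cohort_median == 0)
    stop("cohort median CVR must be nonzero")
  d <- dim(pairs[[1]]$test)
  acc <- array(0, d); cnt <- array(0, d)
  for (p in pairs) {
    dd <- abs(p$test - p$retest) / cohort_median
    okv <- is.finite(dd)
    acc[okv] <- acc[okv] + dd[okv]
    cnt[okv] <- cnt[okv] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Amplitude spectrum of a series
#'
#' Mean-removed, zero-padded discrete Fourier magnitude, normalized to its
#' maximum; frequencies in Hz up to Nyquist. Padding (default to 4096 s)
#' localizes protocol peaks off the coarse 1/duration grid.
#'
#' @param s a \linkS4class{SampledSeries} of length >= 8.
#' @param pad_to_s total padded duration in seconds.
#' @return data.frame with \code{frequency_hz} and \code{amplitude}.
#' @export
amplitudeSpectrum <- function(s, pad_to_s = 4096) {
  stopifnot(is(s, "SampledSeries"))
  v <- s@values - mean(s@values)
  n <- length(v)
  if (n < 8) stop("series too short for a spectrum (need >= 8 samples)")
  npad <- max(n, ceiling(pad_to_s / s@dt))
  X <- fft(c(v, numeric(npad - n)))
  half <- seq_len(floor(npad / 2) + 1L)
  amp <- Mod(X[half])
  if (max(amp) > 0) amp <- amp / max(amp)
  data.frame(frequency_hz = (half - 1) / (npad * s@dt), amplitude = amp)
}

#' Normalized autocorrelation and its first local minimum
#'
#' Autocorrelation over lags 0..\code{max_lag_s} (1 at lag 0). The first
#' local minimum is the smallest lag where the discrete derivative changes
#' sign from negative to positive; a plateau (absolute derivative below
#' \code{plateau_tol} for >= 3 consecutive lags) also qualifies. This lag is
#' the paradigm-specific safe bound for delay alignment.
#'
#' @param s a \linkS4class{SampledSeries}.
#' @param max_lag_s maximum lag in seconds (< duration / 2).
#' @param plateau_tol per-lag derivative tolerance for plateau detection.
#' @return list with \code{lag_s}, \code{acf}, \code{first_min_lag_s},
#'   \code{first_min_value}.
#' @export
autocorrelationSeries <- function(s, max_lag_s, plateau_tol = 0.005) {
  stopifnot(is(s, "SampledSeries"))
  dur <- (length(s@values) - 1) * s@dt
  if (max_lag_s >= dur / 2) stop("max_lag_s must be < duration / 2")
  K <- floor(max_lag_s / s@dt)
  ac <- as.numeric(acf(s@values, lag.max = K, plot = FALSE,
                       demean = TRUE)$acf)
  dv <- diff(ac)
  firstMin <- NA_integer_
  descended <- FALSE   # a plateau only counts after a real descent
  for (i in seq_len(length(dv) - 1)) {
    if (dv[i] < -plateau_tol) descended <- TRUE
    if (dv[i] < 0 && dv[i + 1] > 0) { firstMin <- i + 1L; break }
    if (descended && i + 2 <= length(dv) &&
        all(abs(dv[i:(i + 2)]) < plateau_tol)) {
      firstMin <- i + 1L; break
    }
  }
  list(lag_s = (seq_len(K + 1) - 1) * s@dt, acf = ac,
       first_min_lag_s = if (is.na(firstMin)) NA_real_ else
         (firstMin - 1) * s@dt,
       first_min_value = if (is.na(firstMin)) NA_real_ else ac[firstMin])
}

#' Repeatability report for one condition
#'
#' Convenience wrapper assembling the per-condition metrics: per-subject
#' spatial ICC(C,1) with Fisher z, within/between/differential correlation,
#' COV and median-scaled absolute-difference maps, over a common valid mask
#' (voxels valid in >= \code{min_frac} of runs).
#'
#' @param results list per subject of \code{list(test = , retest = )}
#'   \linkS4class{CVRResult}s.
#' @param condition label for the report.
#' @param min_frac valid-mask fraction rule (default 0.5).
#' @return a \linkS4class{RepeatabilityReport}.
#' @export
repeatabilityReport <- function(results, condition = "", min_frac = 0.5) {
  vols <- unlist(lapply(results, function(p)
    list(p$test@valid, p$retest@valid)), recursive = FALSE)
  cm <- commonValidMask(vols, min_frac)
  maps <- lapply(results, function(p)
    list(test = p$test@cvr, retest = p$retest@cvr))
  icc <- vapply(maps, function(m) {
    sel <- cm & is.finite(m$test) & is.finite(m$retest)
    iccC1(m$test[sel], m$retest[sel])
  }, 1)
  dc <- differentialCorrelation(maps, cm)
  pairsNA <- lapply(maps, function(m) {
    t1 <- m$test; t1[!cm] <- NA; t2 <- m$retest; t2[!cm] <- NA
    list(test = t1, retest = t2)
  })
  allRuns <- unlist(lapply(pairsNA, function(p) list(p$test, p$retest)),
                    recursive = FALSE)
  new("RepeatabilityReport",
      perSubjectICC = unname(icc), fisherZ = unname(fisherZ(icc)),
      withinCorr = dc$within, betweenCorr = dc$between,
      differentialCorr = dc$differential,
      covMap = covMap(allRuns),
      absdiffMap = scaledAbsDiffMap(pairsNA),
      condition = condition)
}
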