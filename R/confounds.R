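#' Expand 6 motion parameters into the 24-term confound set
#'
#' The 6 rigid-body parameters (x, y, z translation and rotation), their
#' temporal derivatives (backward difference, first sample 0) and the squares
#' of those 12 series: exactly 24 confound series.
#'
#' @param motion list of 6 \linkS4class{SampledSeries}.
#' @return named list of 24 \linkS4class{SampledSeries}.
#' @export
expandMotionConfounds <- function(motion) {
  if (length(motion) != 6L) stop("expected exactly 6 motion series")
  n <- vapply(motion, function(s) length(s@values), 1L)
  if (length(unique(n)) != 1L) stop("motion series have unequal lengths")
  base <- lapply(motion, identity)
  deriv <- lapply(motion, function(s)
    initialize(s, values = c(0, diff(s@values)),
               label = paste0(s@label, "_derivative1")))
  firstTwelve <- c(base, deriv)
  squares <- lapply(firstTwelve, function(s)
    initialize(s, values = s@values^2, label = paste0(s@label, "_power2")))
  out <- c(firstTwelve, squares)
  setNames(out, vapply(out, function(s) s@label, ""))
}

#' Screen confounds by correlation with the main regressor
#'
#' A confound is retained iff its absolute Pearson correlation with the
#' regressor is strictly below the threshold: threshold 0 retains nothing
#' (no motion-confounds, the default), threshold 1 retains everything short
#' of exact collinearity. Constant confounds are dropped with a warning.
#'
#' @param confounds list of \linkS4class{SampledSeries}.
#' @param regressor the main regressor (\linkS4class{SampledSeries} or numeric).
#' @param threshold real in [0, 1].
#' @return the retained subset of \code{confounds}.
#' @export
screenConfounds <- function(confounds, regressor, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0,1]")
  if (threshold == 0) return(confounds[integer(0)])
  r <- if (is(regressor, "SampledSeries")) regressor@values else
    as.numeric(regressor)
  keep <- vapply(confounds, function(cf) {
    v <- if (is(cf, "SampledSeries")) cf@values else as.numeric(cf)
    if (sd(v) == 0) {
      warning("dropping constant confound", call. = FALSE)
      return(FALSE)
    }
    abs(cor(v[seq_len(min(length(v), length(r)))],
            r[seq_len(min(length(v), length(r)))])) < threshold
  }, TRUE)
  confounds[keep]
}

#' Coefficient of determination of the regressor on a confound set
#'
#' OLS of the regressor (dependent) on the confounds plus intercept;
#' rank-deficient confound sets are handled by pivoted elimination. Values
#' near 1 mean the confound set absorbs the stimulus-driven signal.
#'
#' @param regressor \linkS4class{SampledSeries} or numeric vector.
#' @param confounds list of \linkS4class{SampledSeries} / numeric vectors.
#' @return R^2 in [0, 1].
#' @export
collinearityR2 <- function(regressor, confounds) {
  y <- if (is(regressor, "SampledSeries")) regressor@values else
    as.numeric(regressor)
  if (!length(confounds)) stop("need at least one confound")
  cols <- lapply(confounds, function(cf)
    if (is(cf, "SampledSeries")) cf@values else as.numeric(cf))
  n <- min(length(y), vapply(cols, length, 1L))
  X <- cbind(1, do.call(cbind, lapply(cols, function(v) v[1:n])))
  y <- y[1:n]
  q <- qr(X)
  keep <- q$pivot[seq_len(q$rank)]
  fit <- lm.fit(X[, keep, drop = FALSE], y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  max(0, min(1, 1 - sum(fit$residuals^2) / tss))
}
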