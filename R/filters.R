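# Zero-phase recursive filtering on matrices (time in rows, channels in
# columns). Forward-backward application of a Butterworth-type IIR filter,
# with odd reflection padding and steady-state initial conditions so that
# constants pass through exactly (DC gain 1, no startup transient).

# steady-state filter state for a unit step input (transposed direct form II)
.lfilterZi <- function(b, a) {
  n <- length(a) - 1L
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  IminusA <- diag(n) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# causal IIR filter with per-column initial state zi * x[1, ]
.lfilterMat <- function(b, a, x, zi) {
  n <- nrow(x); nc <- ncol(x); ord <- length(a) - 1L
  y <- matrix(0, n, nc)
  Z <- outer(zi, x[1, ])
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1] * xt + Z[1, ]
    if (ord > 1L)
      for (i in seq_len(ord - 1L))
        Z[i, ] <- b[i + 1L] * xt + Z[i + 1L, ] - a[i + 1L] * yt
    Z[ord, ] <- b[ord + 1L] * xt - a[ord + 1L] * yt
    y[t, ] <- yt
  }
  y
}

# forward-backward (zero-phase) filtering with odd end extension
.filtfiltMat <- function(b, a, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  padlen <- 3L * max(length(a), length(b))
  if (n <= padlen)
    stop("series too short for zero-phase filtering (need > ", padlen,
         " samples)")
  zi <- .lfilterZi(b, a)
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[(n - 1L):(n - padlen), , drop = FALSE]
  ext <- rbind(top, x, bot)
  y <- .lfilterMat(b, a, ext, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- .lfilterMat(b, a, y, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(padlen + 1L):(padlen + n), , drop = FALSE]
}

# Butterworth low-pass coefficients for a cutoff in mHz at sampling interval dt
.lowpassCoefs <- function(cutoff_mhz, dt, order = 5L) {
  fc <- cutoff_mhz / 1000
  nyq <- 1 / (2 * dt)
  if (fc >= nyq)
    stop(sprintf(
      "low-pass cutoff %.4g mHz is at/above the Nyquist frequency %.4g mHz; use Inf to disable the filter",
      cutoff_mhz, nyq * 1000))
  bf <- signal::butter(order, fc / nyq, type = "low")
  list(b = bf$b, a = bf$a)
}
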