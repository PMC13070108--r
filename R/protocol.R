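#' Build the stimulus protocol of a vascular paradigm
#'
#' All three paradigms span one 5-minute (300 s) run:
#' \itemize{
#'   \item \strong{CO2}: 30 s baseline, then two 60 s blocks of 5% CO2
#'     inhalation, each followed by 75 s of room air.
#'   \item \strong{BH}: 60 s paced breathing, then three 15 s end-expiratory
#'     breath-holds each followed by 45 s paced breathing, closing with a
#'     final 60 s paced block (holds start every 60 s; total 300 s).
#'   \item \strong{RS}: a single 300 s resting block, level constant.
#' }
#'
#' @param paradigm "CO2", "BH" or "RS".
#' @return a \linkS4class{StimulusProtocol}.
#' @export
buildProtocol <- function(paradigm) {
  blocks <- switch(paradigm,
    CO2 = data.frame(
      name = c("baseline", "stim", "rest", "stim", "rest"),
      duration_s = c(30, 60, 75, 60, 75),
      level = c(0, 1, 0, 1, 0)),
    BH = data.frame(
      name = c("paced", "hold", "paced", "hold", "paced", "hold", "paced",
               "paced"),
      duration_s = c(60, 15, 45, 15, 45, 15, 45, 60),
      level = c(0, 1, 0, 1, 0, 1, 0, 0)),
    RS = data.frame(name = "rest", duration_s = 300, level = 0),
    stop("unknown paradigm: ", paradigm, " (expected CO2, BH or RS)"))
  new("StimulusProtocol", blocks = blocks, paradigm = paradigm)
}

#' Convert a protocol into an end-tidal CO2 regressor trace
#'
#' Produces the mmHg-scale ET-CO2 trace a subject following the protocol
#' would show, sampled at \code{dt_s}:
#' \itemize{
#'   \item CO2: boxcar at the stimulus level, scaled to
#'     \code{amplitude_mmhg}, smoothed by a causal single-exponential
#'     response kernel (time constant \code{tau_s}).
#'   \item BH: linear ET-CO2 rise over each 15 s hold to
#'     \code{amplitude_mmhg}, then exponential return to baseline, smoothed
#'     by the same kernel.
#'   \item RS: stochastic trace, a slow random walk plus a band-limited
#'     respiratory oscillation with cycle length drawn uniformly in 5--8 s;
#'     deterministic given \code{seed}.
#' }
#'
#' @param p a \linkS4class{StimulusProtocol}.
#' @param dt_s sampling interval in seconds.
#' @param seed integer seed (used by the RS paradigm).
#' @param baseline_mmhg resting ET-CO2 level (mmHg).
#' @param amplitude_mmhg stimulus-evoked ET-CO2 excursion (mmHg). No
#'   physiological default is claimed; 8 mmHg is a plausible response to 5%
#'   CO2 inhalation, 5 mmHg to a 15 s hold, and 2 mmHg the scale of resting
#'   fluctuations.
#' @param tau_s response-kernel time constant in seconds (default 8).
#' @return a \linkS4class{SampledSeries} in mmHg.
#' @export
protocolToRegressor <- function(p, dt_s, seed = 1L, baseline_mmhg = 40,
                                amplitude_mmhg = NULL, tau_s = 8) {
  stopifnot(is(p, "StimulusProtocol"), dt_s > 0)
  if (is.null(amplitude_mmhg))
    amplitude_mmhg <- switch(p@paradigm, CO2 = 8, BH = 5, RS = 2)
  total <- sum(p@blocks$duration_s)
  n <- as.integer(ceiling(total / dt_s - 1e-9))
  t <- (seq_len(n) - 1L) * dt_s
  x <- switch(p@paradigm,
    CO2 = .boxcarLevels(p, t) * amplitude_mmhg,
    BH = .bhRamp(p, t) * amplitude_mmhg,
    RS = .rsFluctuation(t, dt_s, seed) * amplitude_mmhg)
  if (p@paradigm != "RS") x <- .expSmooth(x, dt_s, tau_s)
  SampledSeries(baseline_mmhg + x, dt = dt_s, t0 = 0,
                label = paste0("etco2_", tolower(p@paradigm)))
}

.blockStarts <- function(p) cumsum(c(0, head(p@blocks$duration_s, -1)))

.boxcarLevels <- function(p, t) {
  starts <- .blockStarts(p)
  ends <- starts + p@blocks$duration_s
  lev <- numeric(length(t))
  for (i in seq_len(nrow(p@blocks)))
    lev[t >= starts[i] & t < ends[i]] <- p@blocks$level[i]
  lev
}

# linear rise over each hold, exponential return afterwards; ET-CO2
# renormalizes within one to two paced breaths once breathing resumes
.bhRamp <- function(p, t, tau_return = 6) {
  starts <- .blockStarts(p)
  ends <- starts + p@blocks$duration_s
  holds <- which(p@blocks$level > 0)
  x <- numeric(length(t))
  for (i in holds) {
    inHold <- t >= starts[i] & t < ends[i]
    x[inHold] <- pmax(x[inHold],
                      p@blocks$level[i] * (t[inHold] - starts[i]) /
                        p@blocks$duration_s[i])
    after <- t >= ends[i]
    x[after] <- pmax(x[after],
                     p@blocks$level[i] * exp(-(t[after] - ends[i]) / tau_return))
  }
  x
}

# resting-state fluctuation: smoothed random walk + respiratory oscillation
.rsFluctuation <- function(t, dt, seed) {
  .withSeed(seed, {
    walk <- cumsum(rnorm(length(t), sd = sqrt(dt)))
    walk <- .expSmooth(walk, dt, tau = 15)
    walk <- walk - mean(walk)
    walk <- walk / max(sd(walk), 1e-12)
    cycle <- runif(1, 5, 8)
    osc <- sin(2 * pi * t / cycle + runif(1, 0, 2 * pi))
    0.6 * walk + 0.4 * osc
  })
}

# causal single-exponential smoothing, y_i = a y_{i-1} + (1-a) x_i
.expSmooth <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter(x * (1 - a), filter = a, method = "recursive",
                           init = x[1]))
}

# evaluate a block with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
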