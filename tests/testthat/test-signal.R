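test_that("EPI mask recovers separable intensities and keeps the largest blob", {
  a <- array(0, c(8, 8, 8, 3))
  a[2:4, 2:4, 2:4, ] <- 100 + rnorm(27 * 3)      # 27-voxel blob
  a[6:7, 6:7, 6:7, ] <- 100 + rnorm(8 * 3)       # 8-voxel blob
  run <- BoldRun(a, dt = 1)
  m <- maskArray(makeEpiMask(run))
  expect_equal(sum(m), 27)
  expect_true(all(m[2:4, 2:4, 2:4]))

  single <- array(0, c(6, 6, 6, 2))
  single[2:4, 2:4, 2:4, ] <- 50
  expect_equal(sum(maskArray(makeEpiMask(BoldRun(single, dt = 1)))), 27)

  expect_error(makeEpiMask(BoldRun(array(0, c(4, 4, 4, 2)), dt = 1)), "empty")
})

test_that("Gaussian smoothing: identity at 0, Gaussian weights, mass and DC preserved", {
  run <- impulseRun()
  expect_identical(boldData(gaussianSmooth(run, 0)), boldData(run))

  sm <- gaussianSmooth(run, 5)        # 3 mm voxels -> sigma = 0.70798 voxels
  frame <- boldData(sm)[, , , 1]
  expect_equal(sum(frame), 1, tolerance = 1e-6)  # interior impulse mass
  sigma <- 5 / (2 * sqrt(2 * log(2))) / 3
  ctr <- 6
  # separable kernel: profile along an axis matches exp(-d^2 / 2 sigma^2)
  prof <- frame[, ctr, ctr] / frame[ctr, ctr, ctr]
  expect_equal(prof[ctr + 1], exp(-0.5 / sigma^2), tolerance = 1e-6)
  expect_equal(prof[ctr + 2], exp(-2 / sigma^2), tolerance = 1e-6)

  const <- BoldRun(array(3.5, c(6, 6, 6, 2)), dt = 1)
  expect_equal(boldData(gaussianSmooth(const, 7)), boldData(const),
               tolerance = 1e-12)
  expect_error(gaussianSmooth(run, -1), ">= 0")
})

test_that("linear resampling is exact on lines and invertible on its own grid", {
  s <- SampledSeries(c(0, 2, 4), dt = 1)
  up <- resampleSeries(s, factor = 2)
  expect_equal(seriesValues(up), c(0, 1, 2, 3, 4))
  expect_equal(samplingInterval(up), 0.5)

  expect_identical(resampleSeries(s, factor = 1), s)

  set.seed(4)
  x <- SampledSeries(cumsum(rnorm(60)), dt = 0.878)
  rt <- resampleSeries(resampleSeries(x, factor = 2), target_dt = 0.878)
  expect_lt(max(abs(seriesValues(rt) - seriesValues(x))), 1e-9)

  expect_error(resampleSeries(s, target_dt = 10), "duration")
  expect_error(resampleSeries(s, factor = 2, target_dt = 1), "exactly one")
})

test_that("polynomial detrending annihilates low-degree trends and is idempotent", {
  t <- seq_len(50)
  line <- SampledSeries(3 + 0.5 * t, dt = 1)
  expect_identical(polynomialDetrend(line, 0), line)
  expect_lt(max(abs(seriesValues(polynomialDetrend(line, 1)))), 1e-10)

  set.seed(5)
  noise <- rnorm(50)
  s <- SampledSeries(2 - 0.3 * t + 0.01 * t^2 + noise, dt = 1)
  got <- seriesValues(polynomialDetrend(s, 2))
  oracle <- residuals(lm(seriesValues(s) ~ poly(t, 2, raw = TRUE)))
  expect_equal(got, unname(oracle), tolerance = 1e-8)

  twice <- polynomialDetrend(polynomialDetrend(s, 2), 2)
  expect_equal(seriesValues(twice), got, tolerance = 1e-10)

  expect_error(polynomialDetrend(SampledSeries(c(1, 2, 3), dt = 1), 3),
               "shorter")
})

test_that("zero-phase low-pass: DC preserved, stop-band attenuated, near-idempotent in-band", {
  const <- SampledSeries(rep(7, 300), dt = 0.439)
  expect_equal(seriesValues(lowpassFilter(const, 116.4)),
               seriesValues(const), tolerance = 1e-9)

  t <- (0:699) * 0.439
  hi <- SampledSeries(sin(2 * pi * 0.3 * t), dt = 0.439)
  out <- lowpassFilter(hi, 116.4)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(seriesValues(out)), 0.15 * rms(seriesValues(hi)))

  lo <- SampledSeries(sin(2 * pi * 0.02 * t), dt = 0.439)  # well inside passband
  once <- lowpassFilter(lo, 116.4)
  twice <- lowpassFilter(once, 116.4)
  # idempotent in-band away from the reflection-padded edges
  mid <- 101:599
  expect_lt(rms(seriesValues(twice)[mid] - seriesValues(once)[mid]), 1e-6)

  expect_error(lowpassFilter(hi, 2000), "Nyquist")
})

test_that("PSC scaling follows its definition and flags non-positive baselines", {
  const <- SampledSeries(rep(5, 10), dt = 1)
  expect_true(all(seriesValues(pscScale(const)) == 0))

  s <- SampledSeries(c(100, 102), dt = 1)
  expect_equal(seriesValues(pscScale(s)),
               c(-100 / 101, 100 / 101), tolerance = 1e-10)

  bad <- SampledSeries(c(-1, 1, -1, 1), dt = 1)   # overall mean 0
  expect_true(all(is.na(seriesValues(pscScale(bad)))))
})

test_that("global signal is the PSC of the summed raw signal", {
  r <- sin(seq(0, 4 * pi, length.out = 40))
  a <- array(0, c(4, 4, 2, 40))
  for (i in 1:4) for (j in 1:4) for (k in 1:2)
    a[i, j, k, ] <- 500 * (1 + 0.01 * r)
  run <- BoldRun(a, dt = 1)
  mask <- BrainMask(array(TRUE, c(4, 4, 2)))
  gs <- globalSignal(run, mask)
  expect_equal(seriesValues(gs), r - mean(r), tolerance = 1e-9)

  # doubling intensities leaves the PSC-scale output unchanged
  run2 <- BoldRun(2 * a, dt = 1)
  expect_equal(seriesValues(globalSignal(run2, mask)), seriesValues(gs),
               tolerance = 1e-9)

  # one-voxel mask equals the PSC of that voxel
  m1 <- array(FALSE, c(4, 4, 2)); m1[1, 1, 1] <- TRUE
  gs1 <- globalSignal(run, BrainMask(m1))
  expect_equal(seriesValues(gs1),
               seriesValues(pscScale(SampledSeries(a[1, 1, 1, ], dt = 1))),
               tolerance = 1e-9)
})

test_that("ET-CO2 alignment recovers constructed lags and clips at the bound", {
  t <- (0:599) * 0.5
  base <- sin(2 * pi * t / 40) + 0.3 * sin(2 * pi * t / 13)
  gs <- SampledSeries(base, dt = 0.5)
  lagged <- SampledSeries(approx(t, base, xout = t - 6, rule = 2)$y, dt = 0.5)
  out <- prepareEtco2(lagged, gs)
  expect_equal(abs(out$shift_s), 6, tolerance = 0.5 + 1e-9)
  expect_false(out$clipped)

  aligned <- prepareEtco2(gs, gs)
  expect_equal(aligned$shift_s, 0)

  far <- SampledSeries(approx(t, base, xout = t - 20, rule = 2)$y, dt = 0.5)
  clipped <- prepareEtco2(far, gs)
  expect_equal(abs(clipped$shift_s), 15, tolerance = 1e-9)
  expect_true(clipped$clipped)

  expect_error(prepareEtco2(SampledSeries(rep(1, 600), dt = 0.5), gs),
               "constant")
})

test_that("sparse ET-CO2 interpolation is linear across breath-hold gaps", {
  s <- interpolateSparseEtco2(c(0, 15), c(40, 46))
  v <- approx(seriesTimes(s), seriesValues(s), xout = 7.5)$y
  expect_equal(v, 43)
  expect_true(all(diff(seriesValues(s)) > 0))   # strictly monotone ramp

  dense <- interpolateSparseEtco2(0:10, 40 + (0:10) * 0.5)
  expect_equal(seriesValues(dense), 40 + (0:10) * 0.5)

  expect_error(interpolateSparseEtco2(c(0, 1), c(40, NA)), "2 valid")
})

test_that("framewise displacement follows the 50 mm small-angle convention", {
  mk <- function(v) SampledSeries(v, dt = 1)
  still <- replicate(6, mk(rep(0, 20)), simplify = FALSE)
  expect_true(all(seriesValues(framewiseDisplacement(still)) == 0))

  step <- still
  step[[1]] <- mk(c(rep(0, 9), rep(1, 11)))      # 1 mm x-step at frame 10
  fd <- seriesValues(framewiseDisplacement(step))
  expect_equal(fd[10], 1)
  expect_true(all(fd[-10] == 0))

  pitch <- still
  pitch[[4]] <- mk(c(rep(0, 9), rep(0.01, 11)))  # 0.01 rad rotation step
  expect_equal(seriesValues(framewiseDisplacement(pitch))[10], 0.5)
})
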