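test_that("ICC(C,1) is 1 for identical and constant-offset sessions", {
  set.seed(13)
  a <- rnorm(50)
  expect_equal(iccC1(a, a), 1)
  expect_equal(iccC1(a, a + 0.7), 1, tolerance = 1e-12)
  expect_error(iccC1(a[1:2], a[1:2]), "at least 3")
})

test_that("ICC(C,1) matches a two-way ANOVA oracle on random instances", {
  set.seed(14)
  for (rep in 1:25) {
    a <- rnorm(50)
    b <- 0.8 * a + rnorm(50, sd = 0.5) + 0.2
    # independent oracle: mean squares from aov's two-way decomposition
    df <- data.frame(y = c(a, b),
                     voxel = factor(rep(1:50, 2)),
                     session = factor(rep(1:2, each = 50)))
    ms <- summary(aov(y ~ voxel + session, df))[[1]][, "Mean Sq"]
    oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3])
    expect_equal(iccC1(a, b), oracle, tolerance = 1e-10)
  }
})

test_that("ICC(C,1) is invariant to affine rescaling and decreases with noise", {
  set.seed(15)
  a <- rnorm(200)
  b <- a + rnorm(200, sd = 0.3)
  base <- iccC1(a, b)
  expect_equal(iccC1(2 * a + 3, 2 * b + 3), base, tolerance = 1e-10)

  noise <- rnorm(200)
  iccs <- vapply(c(0.2, 0.6, 1.5), function(s) iccC1(a, a + s * noise), 1)
  expect_true(all(diff(iccs) < 0))
})

test_that("Fisher z is atanh with clamping", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), atanh(0.5))
  expect_true(all(diff(fisherZ(seq(-0.9, 0.9, by = 0.1))) > 0))
  expect_warning(z <- fisherZ(1), "clamped")
  expect_lt(z, Inf)
})

test_that("map correlation respects affine relations and sampling bounds", {
  set.seed(16)
  a <- array(rnorm(1e4), c(100, 10, 10))
  expect_equal(mapCorrelation(a, 2 * a + 1), 1, tolerance = 1e-12)
  expect_equal(mapCorrelation(a, -a), -1, tolerance = 1e-12)
  b <- array(rnorm(1e4), c(100, 10, 10))
  expect_lt(abs(mapCorrelation(a, b)), 0.05)
})

test_that("differential correlation separates identical from subject-unique cohorts", {
  sh <- c(8, 8, 4)
  set.seed(17)
  shared <- array(rnorm(prod(sh)), sh)
  same <- lapply(1:3, function(i) list(test = shared, retest = shared))
  dc <- differentialCorrelation(same)
  expect_equal(dc$within, 1, tolerance = 1e-12)
  expect_equal(dc$between, 1, tolerance = 1e-12)
  expect_equal(dc$differential, 0, tolerance = 1e-12)
  expect_equal(dc$differential, dc$within - dc$between)   # exact identity

  uniq <- lapply(1:3, function(i) {
    m <- array(rnorm(prod(sh)), sh)
    list(test = m, retest = m)
  })
  du <- differentialCorrelation(uniq)
  expect_equal(du$within, 1, tolerance = 1e-12)
  expect_lt(abs(du$between), 0.2)
  expect_gt(du$differential, 0.8)

  noise <- lapply(1:3, function(i)
    list(test = array(rnorm(prod(sh)), sh),
         retest = array(rnorm(prod(sh)), sh)))
  expect_lt(abs(differentialCorrelation(noise)$differential), 0.2)

  expect_error(differentialCorrelation(same[1]), "2 subjects")
})

test_that("COV map is SD over |mean|, capped at 1", {
  mk <- function(v) array(v, c(1, 1, 1))
  expect_equal(covMap(list(mk(2), mk(2)))[1], 0)
  expect_equal(covMap(list(mk(1), mk(-1)))[1], 1)
  expect_equal(covMap(list(mk(9), mk(11)))[1], sd(c(9, 11)) / 10,
               tolerance = 1e-12)
})

test_that("scaled absolute difference is |test-retest| over the cohort median", {
  sh <- c(2, 2, 1)
  t1 <- array(0.5, sh); t2 <- array(0.3, sh)
  pairs <- list(list(test = t1, retest = t2))
  med <- median(c(t1, t2))
  out <- scaledAbsDiffMap(pairs)
  expect_equal(out[1], 0.2 / med, tolerance = 1e-12)
  expect_equal(scaledAbsDiffMap(list(list(test = t1, retest = t1)))[1], 0)
  # invariant to global rescaling
  sc <- scaledAbsDiffMap(list(list(test = 3 * t1, retest = 3 * t2)))
  expect_equal(sc, out, tolerance = 1e-12)
})

test_that("amplitude spectrum localizes a pure tone", {
  t <- (0:299) * 0.5
  s <- SampledSeries(sin(2 * pi * 0.1 * t), dt = 0.5)
  sp <- amplitudeSpectrum(s)
  pk <- sp$frequency_hz[which.max(sp$amplitude)]
  expect_lt(abs(pk - 0.1), 2 / 4096)      # within two padded bins
  expect_equal(max(sp$amplitude), 1)
})

test_that("low-passed series carry under 1% of energy above 1.5x the cutoff", {
  # long series so finite-window spectral leakage does not dominate the tail
  set.seed(18)
  s <- SampledSeries(rnorm(6000), dt = 0.439)
  f <- 0.1164
  out <- amplitudeSpectrum(lowpassFilter(s, f * 1000), pad_to_s = 6000 * 0.439)
  pw <- out$amplitude^2
  expect_lt(sum(pw[out$frequency_hz > 1.5 * f]) / sum(pw), 0.01)
})

test_that("autocorrelation is normalized and finds first minima like brute force", {
  set.seed(19)
  wn <- SampledSeries(rnorm(400), dt = 1)
  ac <- autocorrelationSeries(wn, 30)
  expect_equal(ac$acf[1], 1)
  expect_true(all(abs(ac$acf[-1]) < 0.2))

  bh <- protocolToRegressor(buildProtocol("BH"), dt_s = 0.878, seed = 1)
  got <- autocorrelationSeries(bh, 50)
  v <- seriesValues(bh) - mean(seriesValues(bh))
  oracle <- vapply(0:56, function(l)
    sum(v[1:(length(v) - l)] * v[(1 + l):length(v)]) / sum(v^2), 1)
  expect_equal(got$acf, oracle, tolerance = 1e-10)
  # first minimum near half the 60 s hold cycle
  expect_gt(got$first_min_lag_s, 20)
  expect_lt(got$first_min_lag_s, 40)

  expect_error(autocorrelationSeries(wn, 300), "duration / 2")
})

test_that("repeatability report assembles consistent per-condition metrics", {
  coh <- smallCohort()
  fits <- lapply(coh$subjects$CO2, fitPairCfg <- function(p)
    list(test = fitSyn(p$test, pipelineConfig()),
         retest = fitSyn(p$retest, pipelineConfig())))
  rep <- repeatabilityReport(fits, condition = "CO2/default")
  expect_length(rep@perSubjectICC, 2)
  expect_true(all(rep@perSubjectICC > 0.5))
  expect_equal(rep@differentialCorr, rep@withinCorr - rep@betweenCorr)
  expect_true(all(rep@covMap[is.finite(rep@covMap)] <= 1))
})
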