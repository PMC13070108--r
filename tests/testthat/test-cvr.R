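mkSeries <- function(v, dt = 1) SampledSeries(v, dt = dt)

test_that("motion expansion yields exactly the 24 canonical confounds", {
  set.seed(6)
  motion <- replicate(6, mkSeries(rnorm(50)), simplify = FALSE)
  out <- expandMotionConfounds(motion)
  expect_length(out, 24)

  zero <- replicate(6, mkSeries(rep(0, 50)), simplify = FALSE)
  expect_true(all(vapply(expandMotionConfounds(zero),
                         function(s) all(seriesValues(s) == 0), TRUE)))

  ramp <- motion
  ramp[[1]] <- mkSeries(0.1 * seq_len(50))
  ex <- expandMotionConfounds(ramp)
  dv <- seriesValues(ex[[7]])           # derivative of parameter 1
  expect_equal(dv[1], 0)
  expect_true(all(abs(dv[-1] - 0.1) < 1e-12))
  expect_equal(seriesValues(ex[[13]]), seriesValues(ramp[[1]])^2)

  expect_error(expandMotionConfounds(motion[1:5]), "6 motion")
})

test_that("confound screening applies a strict correlation threshold", {
  set.seed(7)
  n <- 200
  reg <- rnorm(n)
  orth <- residuals(lm(rnorm(n) ~ reg))
  mix <- function(r) {
    v <- r * scale(reg)[, 1] + sqrt(1 - r^2) * scale(orth)[, 1]
    mkSeries(v)
  }
  confs <- list(low = mix(0.3), high = mix(0.7), copy = mkSeries(reg),
                const = mkSeries(rep(1, n)))

  expect_length(screenConfounds(confs, mkSeries(reg), 0), 0)
  expect_warning(kept1 <- screenConfounds(confs, mkSeries(reg), 1),
                 "constant")
  expect_setequal(names(kept1), c("low", "high"))   # |r|=1 copy excluded
  expect_warning(kept05 <- screenConfounds(confs, mkSeries(reg), 0.5),
                 "constant")
  expect_setequal(names(kept05), "low")
})

test_that("regressor-on-confounds R2 has the right endpoints", {
  set.seed(8)
  n <- 100
  reg <- rnorm(n)
  orth <- lapply(1:3, function(i) residuals(lm(rnorm(n) ~ reg)))
  expect_lt(collinearityR2(reg, orth), 0.15)
  expect_equal(collinearityR2(reg, c(orth, list(reg))), 1, tolerance = 1e-10)
})

test_that("voxel delay estimation recovers constructed shifts with tie-breaking", {
  t <- (0:499) * 0.5
  g <- sin(2 * pi * t / 50) + 0.4 * sin(2 * pi * t / 17)
  reg <- mkSeries(g, dt = 0.5)

  noShift <- estimateVoxelDelay(mkSeries(g, dt = 0.5), reg, 0)
  expect_equal(noShift$delay_s, 0)
  expect_identical(seriesValues(noShift$regressor), g)

  bold <- mkSeries(approx(t, g, xout = t - 6, rule = 2)$y, dt = 0.5)
  got <- estimateVoxelDelay(bold, reg, 15)
  expect_equal(got$delay_s, 6, tolerance = 0.5 + 1e-9)
  expect_gt(got$r, 0.99)

  inv <- estimateVoxelDelay(mkSeries(-g, dt = 0.5), reg, 15)
  expect_equal(inv$delay_s, 0)          # |r| maximum with negative slope
  expect_lt(inv$r, -0.99)
})

test_that("voxel OLS matches exact models and a normal-equations oracle", {
  set.seed(9)
  n <- 80
  g <- rnorm(n)
  fit <- fitVoxel(mkSeries(2 * g + 0.5), mkSeries(g))
  expect_equal(fit$beta, 2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  orth <- residuals(lm(rnorm(n) ~ g))
  f0 <- fitVoxel(mkSeries(orth), mkSeries(g))
  expect_lt(abs(f0$beta), 0.1)
  expect_lt(f0$r2, 0.05)

  cf <- rnorm(n)
  y <- g + cf + rnorm(n, sd = 0.1)
  f1 <- fitVoxel(mkSeries(y), mkSeries(g), list(mkSeries(cf)))
  oracle <- coef(lm(y ~ g + cf))
  expect_equal(f1$beta, unname(oracle["g"]), tolerance = 1e-8)
})

test_that("batched OLS agrees with lm on random small designs", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(30:60, 1)
    p <- sample(0:3, 1)
    X <- cbind(1, rnorm(n), if (p > 0) matrix(rnorm(n * p), n) else NULL)
    Y <- matrix(rnorm(n * 3), n)
    got <- boldcvr:::.olsBatch(Y, X)
    for (j in 1:3) {
      m <- summary(lm(Y[, j] ~ X[, -1]))
      expect_equal(got$beta[j], unname(coef(m)[2, 1]), tolerance = 1e-8)
      expect_equal(got$tvalue[j], unname(coef(m)[2, 3]), tolerance = 1e-6)
      expect_equal(got$r2[j], m$r.squared, tolerance = 1e-8)
    }
  }
  # duplicated regressor column: collinear confound dropped, regressor kept
  g <- rnorm(40)
  Xdup <- cbind(1, g, g)
  res <- boldcvr:::.olsBatch(matrix(2 * g, ncol = 1), Xdup)
  expect_true(res$valid[1])
  expect_equal(res$beta[1], 2, tolerance = 1e-8)
})

test_that("MAD filter excludes only extreme modified-z values", {
  set.seed(11)
  x <- rnorm(1e4)
  valid <- rep(TRUE, 1e4)
  expect_equal(sum(valid) - sum(madOutlierFilter(x, valid, 10)), 0)

  x[1] <- median(x) + 50 * 1.4826 * median(abs(x - median(x)))
  out <- madOutlierFilter(x, valid, 10)
  expect_false(out[1])
  expect_equal(sum(!out), 1)

  const <- rep(2, 100)
  expect_true(all(madOutlierFilter(const, rep(TRUE, 100), 10)))
})

test_that("quality quantile filter removes exactly the lowest fraction", {
  metric <- 1:100
  valid <- rep(TRUE, 100)
  out <- qualityQuantileFilter(valid, metric, 0.10)
  expect_equal(sum(!out), 10)
  expect_true(all(which(!out) == 1:10))
  # second pass removes ~q of the remainder (recomputed quantile)
  out2 <- qualityQuantileFilter(out, metric, 0.10)
  expect_equal(sum(out) - sum(out2), 9)
})

test_that("tSNR is mean over SD on raw data and scale invariant", {
  a <- array(rnorm(4 * 4 * 2 * 50, mean = 100, sd = 2), c(4, 4, 2, 50))
  run <- BoldRun(a, dt = 1)
  ts <- tsnrMap(run)
  v <- a[1, 1, 1, ]
  expect_equal(ts[1, 1, 1], mean(v) / sd(v), tolerance = 1e-10)
  ts2 <- tsnrMap(BoldRun(3 * a, dt = 1))
  expect_equal(ts2, ts, tolerance = 1e-10)

  aconst <- a; aconst[2, 2, 1, ] <- 7
  expect_true(is.na(tsnrMap(BoldRun(aconst, dt = 1))[2, 2, 1]))
})

test_that("tissue normalization rescales to a unit reference mean", {
  sh <- c(6, 6, 4)
  lab <- array(0L, sh); lab[2:5, 2:5, 2:3] <- 1L; lab[3:4, 3:4, 2] <- 2L
  cvr <- array(NA_real_, sh)
  cvr[lab == 1L] <- 0.3; cvr[lab == 2L] <- 0.1
  valid <- lab > 0L
  mk <- function(cvr) new("CVRResult", cvr = cvr, delay = array(0, sh),
                          r2 = array(0.5, sh), tvalue = array(1, sh),
                          rcorr = array(0.5, sh), valid = valid,
                          grid = VoxelGrid(sh), paradigm = "CO2",
                          session = "test", subjectID = "s",
                          regressorKind = "etco2", regressorShift = 0,
                          configDigest = "x")
  res <- mk(cvr)
  wb <- normalizeMap(res, "WB")
  expect_equal(mean(cvrMap(wb)[valid]), 1, tolerance = 1e-9)
  gm <- normalizeMap(res, "GM", lab)
  expect_equal(mean(cvrMap(gm)[lab == 1L]), 1, tolerance = 1e-9)
  expect_equal(mean(cvrMap(gm)[lab == 2L]), 0.1 / 0.3, tolerance = 1e-9)
  # scale equivariance
  sc <- normalizeMap(mk(3 * cvr), "WB")
  expect_equal(cvrMap(sc), cvrMap(wb), tolerance = 1e-12)
})

test_that("3x3x3 delay median filter matches a brute-force neighborhood oracle", {
  sh <- c(6, 5, 4)
  const <- array(2, sh)
  valid <- array(TRUE, sh)
  expect_equal(medianFilterDelays(const, valid), const)

  spike <- array(0, sh); spike[3, 3, 2] <- 60
  expect_equal(medianFilterDelays(spike, valid)[3, 3, 2], 0)

  set.seed(12)
  cb <- array(ifelse((slice.index(array(0, sh), 1) +
                        slice.index(array(0, sh), 2) +
                        slice.index(array(0, sh), 3)) %% 2 == 0, 4, -4), sh)
  vr <- array(runif(prod(sh)) > 0.2, sh)
  got <- medianFilterDelays(cb, vr)
  oracle <- cb
  for (x in 1:sh[1]) for (y in 1:sh[2]) for (z in 1:sh[3]) {
    if (!vr[x, y, z]) next
    xs <- max(1, x - 1):min(sh[1], x + 1)
    ys <- max(1, y - 1):min(sh[2], y + 1)
    zs <- max(1, z - 1):min(sh[3], z + 1)
    nb <- cb[xs, ys, zs][vr[xs, ys, zs]]
    oracle[x, y, z] <- median(nb)
  }
  expect_equal(got, oracle)
})

test_that("common valid mask applies the inclusive fraction rule", {
  sh <- c(3, 3, 1)
  mk <- function(on) { a <- array(FALSE, sh); a[on] <- TRUE; a }
  vols <- list(mk(1:5), mk(2:6), mk(2:3), mk(2))
  cm <- commonValidMask(vols, 0.5)
  expect_false(cm[1])                 # valid in 1/4 -> dropped
  expect_true(cm[2])                  # valid in 4/4
  expect_true(cm[3])                  # valid in 3/4
  expect_true(cm[5])                  # valid in exactly 2/4 -> kept (inclusive)
  expect_false(cm[6])                 # valid in 1/4 -> dropped
  strict <- commonValidMask(vols, 1)
  expect_equal(which(strict), 2L)     # strict intersection
})
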