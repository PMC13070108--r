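test_that("NIfTI volume round-trips are bit-identical with geometry", {
  set.seed(1)
  a <- array(rnorm(8 * 8 * 4 * 20), c(8, 8, 4, 20))
  run <- BoldRun(a, grid = VoxelGrid(c(8, 8, 4), voxelSize = c(2.5, 2.5, 3)),
                 dt = 0.878)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(run, f)
  back <- readVolume(f)
  expect_s4_class(back, "BoldRun")
  expect_identical(dim(boldData(back)), dim(a))
  expect_equal(as.vector(boldData(back)), as.vector(a))
  expect_equal(voxelGrid(back)@voxelSize, c(2.5, 2.5, 3))
  expect_equal(samplingInterval(back), 0.878, tolerance = 1e-6)
})

test_that("3-D label volumes keep integer labels exactly", {
  set.seed(2)
  lab <- array(sample(0:3, 8 * 8 * 4, TRUE), c(8, 8, 4))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(lab, f, grid = VoxelGrid(c(8, 8, 4)))
  back <- readVolume(f)
  expect_true(all(back == lab))
})

test_that("readVolume rejects missing files and honours a dt override", {
  expect_error(readVolume(tempfile()), "not found")
  suppressWarnings(expect_error(readVolume({
    f <- tempfile(fileext = ".nii"); writeLines("not a nifti", f); f
  }, dt = 1), "NIfTI"))
  a <- array(rnorm(4 * 4 * 2 * 5), c(4, 4, 2, 5))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(BoldRun(a, dt = 0.878), f)
  expect_equal(samplingInterval(readVolume(f, dt = 1.2)), 1.2)
})

test_that("timeseries tables preserve shape, missing markers, and reject bad cells", {
  df <- as.data.frame(matrix(rnorm(341 * 6), 341, 6))
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- readTimeseriesTable(f, dt = 0.878)
  expect_length(out, 6)
  expect_true(all(vapply(out, function(s) length(seriesValues(s)), 1L) == 341))
  expect_equal(samplingInterval(out$trans_x), 0.878)

  # one missing cell becomes one NA of the same length
  lines <- readLines(f)
  parts <- strsplit(lines[3], "\t")[[1]]
  parts[2] <- "n/a"
  lines[3] <- paste(parts, collapse = "\t")
  writeLines(lines, f)
  out2 <- readTimeseriesTable(f, dt = 0.878)
  expect_equal(sum(is.na(seriesValues(out2$trans_y))), 1)
  expect_length(seriesValues(out2$trans_y), 341)

  # non-numeric cell (not the missing token) is an error
  parts[3] <- "abc"
  lines[3] <- paste(parts, collapse = "\t")
  writeLines(lines, f)
  expect_error(readTimeseriesTable(f, dt = 0.878), "non-numeric")

  # ragged rows are an error
  writeLines(c("a\tb", "1\t2", "3"), f)
  expect_error(readTimeseriesTable(f, dt = 1), "ragged")
})

test_that("series round-trip through a table preserves values at write precision", {
  s <- list(etco2 = SampledSeries(c(40, 42.5, NA, 41), dt = 1))
  f <- tempfile(fileext = ".tsv")
  writeTimeseriesTable(s, f)
  back <- readTimeseriesTable(f, dt = 1)
  expect_equal(seriesValues(back$etco2), c(40, 42.5, NA, 41))
})

test_that("empty config yields the documented defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- loadConfig(f)
  expect_equal(cfg@fwhm_mm, 5)
  expect_equal(cfg@detrend_order, 1L)
  expect_equal(cfg@lowpass_mhz, 116.4)
  expect_equal(cfg@upsample_factor, 2L)
  expect_equal(cfg@confound_corr_threshold, 0)
  expect_equal(cfg@max_delay_s, 0)
  expect_equal(cfg@mad_z_threshold, 10)
  expect_equal(cfg@quality_metric, "none")
  expect_equal(cfg@baseline_strategy, "overall_mean")
  expect_equal(cfg@trim_initial_s, 15)
})

test_that("out-of-range config values name the key and its legal range", {
  expect_error(pipelineConfig(detrend_order = 5), "detrend_order")
  expect_error(pipelineConfig(detrend_order = 5), "0..3", fixed = TRUE)
  expect_error(pipelineConfig(upsample_factor = 9), "1..4", fixed = TRUE)
  expect_error(pipelineConfig(confound_corr_threshold = 1.5), "\\[0,1\\]")
  expect_error(pipelineConfig(nonsense = 1), "unknown")
})

test_that("'inf' disables the low-pass filter and delay bound", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("lowpass_mhz: inf", "max_delay_s: .inf"), f)
  cfg <- loadConfig(f)
  expect_identical(cfg@lowpass_mhz, Inf)
  expect_identical(cfg@max_delay_s, Inf)
  s <- SampledSeries(rnorm(50), dt = 0.5)
  expect_identical(seriesValues(lowpassFilter(s, Inf)), seriesValues(s))
})

test_that("config digests key the exact parameter set", {
  a <- configDigest(pipelineConfig())
  b <- configDigest(pipelineConfig(fwhm_mm = 5))
  c <- configDigest(pipelineConfig(fwhm_mm = 4))
  expect_identical(a, b)
  expect_false(identical(a, c))
})
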