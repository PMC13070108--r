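# Shared fixtures: built once per test run and cached, so several test files
# can reuse the same synthetic cohorts without regenerating them.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# a small, fast cohort for unit tests of the experiment drivers
smallCohort <- function() {
  cachedFixture("smallCohort", function()
    generateCohort(2, "CO2", seed = 402, shape = c(12L, 12L, 8L),
                   noise_sd = 20))
}

# default-conditions CO2 cohort used by the smoothing / repeatability checks
defaultCO2Cohort <- function() {
  cachedFixture("defaultCO2Cohort", function()
    generateCohort(3, "CO2", seed = 301))
}

fitSyn <- function(run, config) {
  fitRun(run@bold, config, etco2 = run@etco2, motion = run@motion)
}

# synthetic impulse run for smoothing tests
impulseRun <- function(shape = c(11L, 11L, 11L), nt = 2L, voxel = c(3, 3, 3)) {
  a <- array(0, c(shape, nt))
  ctr <- (shape + 1) %/% 2
  a[ctr[1], ctr[2], ctr[3], ] <- 1
  BoldRun(a, grid = VoxelGrid(shape, voxel), dt = 1)
}
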