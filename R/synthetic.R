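#' Parameters of the synthetic cohort generator
#'
#' Returns the full parameter set describing one simulated acquisition
#' condition, with defaults emulating the study conditions: 5-min runs at a
#' 0.878 s repetition interval on a 24 x 24 x 12 grid of 3 mm voxels,
#' ET-CO2 sampled at 1 Hz, gray-matter reactivity above white matter,
#' tissue-dependent hemodynamic delays, polynomial drift, motion-coupled
#' artifacts scaled to paradigm-typical mean framewise displacement
#' (CO2 0.12 mm, BH 0.14 mm, RS 0.11 mm) and white noise.
#'
#' @param paradigm "CO2", "BH" or "RS".
#' @param ... overrides for any returned element.
#' @return named list of generator parameters:
#' \describe{
#'   \item{shape, voxel_mm, dt_s, duration_s}{grid geometry and timing.}
#'   \item{etco2_dt_s}{ET-CO2 sampling interval (1 s).}
#'   \item{etco2_baseline_mmhg, etco2_amplitude_mmhg, kernel_tau_s}{regressor
#'     construction (see \code{\link{protocolToRegressor}}).}
#'   \item{amp_pct_per_mmhg}{named GM/WM/CSF mean CVR amplitude, % per mmHg.}
#'   \item{baseline_intensity}{named GM/WM/CSF baseline signal level.}
#'   \item{cvr_jitter_sd}{relative SD of smooth spatial CVR variation.}
#'   \item{delay_mean_s, delay_jitter_sd_s, delay_scale}{tissue-mean delays
#'     (GM 1 s, WM 4 s, CSF 2 s), smooth jitter, and a global scale (0
#'     disables delays).}
#'   \item{drift_sd}{SD of the fractional linear/quadratic drift coefficients.}
#'   \item{mean_fd_mm}{target mean framewise displacement of the motion traces.}
#'   \item{motion_coupling_sd}{SD of per-voxel fractional motion coupling.}
#'   \item{noise_sd}{white-noise SD in raw intensity units.}
#'   \item{retest_scale}{global amplitude factor applied to the retest run
#'     (0.95, emulating the small test-to-retest CVR decrease).}
#' }
#' @export
cohortParams <- function(paradigm = "CO2", ...) {
  paradigm <- match.arg(paradigm, c("CO2", "BH", "RS"))
  p <- list(
    paradigm = paradigm,
    shape = c(24L, 24L, 12L),
    voxel_mm = c(3, 3, 3),
    dt_s = 0.878,
    duration_s = 300,
    etco2_dt_s = 1,
    etco2_baseline_mmhg = 40,
    etco2_amplitude_mmhg = switch(paradigm, CO2 = 8, BH = 5, RS = 2),
    kernel_tau_s = 8,
    amp_pct_per_mmhg = c(GM = 0.30, WM = 0.10, CSF = 0.05),
    baseline_intensity = c(GM = 1000, WM = 900, CSF = 700),
    cvr_jitter_sd = 0.10,
    delay_mean_s = c(GM = 1, WM = 4, CSF = 2),
    delay_jitter_sd_s = 1,
    delay_scale = 1,
    drift_sd = 0.005,
    mean_fd_mm = switch(paradigm, CO2 = 0.12, BH = 0.14, RS = 0.11),
    motion_coupling_sd = 0.005,
    noise_sd = 10,
    retest_scale = 0.95)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown cohort parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (any(p$noise_sd < 0)) stop("noise_sd must be non-negative")
  p
}

# nested-ellipsoid phantom: 1 GM shell, 2 WM core, 3 CSF ventricle
.phantomLabels <- function(shape) {
  u <- lapply(1:3, function(ax)
    (seq_len(shape[ax]) - (shape[ax] + 1) / 2) / (0.45 * shape[ax]))
  r2 <- outer(outer(u[[1]]^2, u[[2]]^2, "+"), u[[3]]^2, "+")
  lab <- array(0L, shape)
  lab[r2 <= 1] <- 1L                         # GM shell
  lab[r2 <= 0.55^2] <- 2L                    # deep WM
  lab[r2 <= 0.18^2] <- 3L                    # central CSF (ventricles)
  lab
}

# smooth standard-normal spatial field (white noise + 1-voxel-sigma smoothing)
.smoothField <- function(shape) {
  a <- array(rnorm(prod(shape)), shape)
  for (ax in 1:3) {
    S <- .gaussSmootherMatrix(shape[ax], 1)
    a <- .applyAlongAxis(a, ax, S)
  }
  s <- sd(a)
  if (s > 0) a <- a / s
  a
}

#' Generate a synthetic test--retest subject
#'
#' Draws one subject's latent maps (CVR amplitude, delay, drift, motion
#' coupling, noise SD on the tissue phantom) and synthesizes a test and a
#' retest run. Voxel signals follow
#' \code{baseline * (1 + cvr * regressor(t - delay)/100 + drift(t) +
#' coupling . motion(t)) + noise}, where the regressor is the mean-centred
#' ET-CO2 excursion in mmHg. The retest run re-draws noise and motion and
#' applies a global amplitude scale < 1; ground truth is recorded and shared
#' by both sessions.
#'
#' @param params parameter list from \code{\link{cohortParams}}.
#' @param subjectID subject identifier.
#' @param seed integer seed; everything is deterministic given it.
#' @return list with elements \code{test} and \code{retest}
#'   (\linkS4class{SyntheticRun}s sharing one \linkS4class{GroundTruth}).
#' @export
generateSubject <- function(params, subjectID = "sub-01", seed = 1L) {
  .withSeed(seed, {
    grid <- VoxelGrid(params$shape, voxelSize = params$voxel_mm)
    labels <- .phantomLabels(params$shape)
    inside <- labels > 0L
    tiss <- c("GM", "WM", "CSF")[pmax(labels, 1L)]

    cvr <- array(0, params$shape)
    cvr[inside] <- params$amp_pct_per_mmhg[tiss[inside]] *
      pmax(1 + params$cvr_jitter_sd * .smoothField(params$shape)[inside], 0.1)

    delay <- array(0, params$shape)
    delay[inside] <- pmax(params$delay_mean_s[tiss[inside]] +
      params$delay_jitter_sd_s * .smoothField(params$shape)[inside], 0)
    delay <- delay * params$delay_scale

    baseline <- array(0, params$shape)
    baseline[inside] <- params$baseline_intensity[tiss[inside]]

    driftC <- array(0, c(params$shape, 2L))
    nIn <- sum(inside)
    for (k in 1:2) {
      sl <- array(0, params$shape)
      sl[inside] <- rnorm(nIn, sd = params$drift_sd)
      driftC[, , , k] <- sl
    }

    coupling <- array(0, c(params$shape, 6L))
    for (k in 1:6) {
      sl <- array(0, params$shape)
      sl[inside] <- rnorm(nIn, sd = params$motion_coupling_sd)
      coupling[, , , k] <- sl
    }

    noiseSD <- array(0, params$shape)
    noiseSD[inside] <- params$noise_sd

    truth <- new("GroundTruth", cvr = cvr, delay = delay, labels = labels,
                 baseline = baseline, driftCoeffs = driftC,
                 motionCoupling = coupling, noiseSD = noiseSD, grid = grid)

    proto <- buildProtocol(params$paradigm)
    sessions <- lapply(c(test = 1L, retest = 2L), function(k) {
      sessSeed <- as.integer((seed * 7L + k * 131L) %% .Machine$integer.max)
      .synthSession(params, truth, proto, grid,
                    session = c("test", "retest")[k],
                    scale = if (k == 2L) params$retest_scale else 1,
                    subjectID = subjectID, seed = sessSeed)
    })
    names(sessions) <- c("test", "retest")
    sessions
  })
}

.synthSession <- function(params, truth, proto, grid, session, scale,
                          subjectID, seed) {
  .withSeed(seed, {
    nt <- as.integer(floor(params$duration_s / params$dt_s + 1e-9))
    tFrame <- (seq_len(nt) - 1L) * params$dt_s
    etco2 <- protocolToRegressor(proto, dt_s = params$etco2_dt_s, seed = seed,
                                 baseline_mmhg = params$etco2_baseline_mmhg,
                                 amplitude_mmhg = params$etco2_amplitude_mmhg,
                                 tau_s = params$kernel_tau_s)
    tE <- seriesTimes(etco2)
    rfun <- function(tt) approx(tE, etco2@values, xout = tt, rule = 2)$y

    motion <- .motionTraces(nt, params$dt_s, params$mean_fd_mm)
    P <- vapply(motion, seriesValues, numeric(nt))

    inside <- truth@labels > 0L
    nIn <- sum(inside)
    b <- truth@baseline[inside]
    cv <- truth@cvr[inside] * scale
    dl <- truth@delay[inside]

    # regressor excursion at delayed frame times, one row per voxel;
    # mean-centred so that the baseline intensity is the temporal mean of
    # the signal (the overall-mean PSC convention the estimator uses)
    tq <- rep(tFrame, each = nIn) - rep(dl, times = nt)
    Rsh <- matrix(rfun(tq), nIn, nt)
    Rsh <- Rsh - rowMeans(Rsh)

    tn <- (tFrame - params$duration_s / 2) / params$duration_s
    c1 <- matrix(truth@driftCoeffs[, , , 1][inside], nIn, 1)
    c2 <- matrix(truth@driftCoeffs[, , , 2][inside], nIn, 1)
    drift <- c1 %*% matrix(tn, 1) + c2 %*% matrix(tn^2, 1)

    W <- vapply(1:6, function(k) truth@motionCoupling[, , , k][inside],
                numeric(nIn))
    art <- W %*% t(P)

    sig <- b * (1 + (cv * Rsh) / 100 + drift + art)
    if (params$noise_sd > 0)
      sig <- sig + matrix(rnorm(nIn * nt, sd = truth@noiseSD[inside]), nIn, nt)

    vol <- array(0, c(params$shape, nt))
    flat <- matrix(vol, prod(params$shape), nt)
    flat[as.vector(inside), ] <- sig
    vol <- array(flat, c(params$shape, nt))

    bold <- BoldRun(vol, grid = grid, dt = params$dt_s,
                    paradigm = params$paradigm, session = session,
                    subjectID = subjectID)
    new("SyntheticRun", bold = bold, etco2 = etco2, motion = motion,
        truth = truth, seed = as.integer(seed))
  })
}

# integrated white noise rescaled to a target mean framewise displacement
.motionTraces <- function(nt, dt, meanFD) {
  labs <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (meanFD <= 0) {
    return(lapply(labs, function(l)
      SampledSeries(numeric(nt), dt = dt, t0 = 0, label = l)))
  }
  M <- vapply(1:6, function(k) {
    s <- cumsum(rnorm(nt))
    if (k > 3) s <- s / 50          # rotations (rad) on the 50 mm convention
    s
  }, numeric(nt))
  d <- abs(apply(M, 2, function(col) c(0, diff(col))))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE])
  M <- M * (meanFD / mean(fd))
  lapply(1:6, function(k) SampledSeries(M[, k], dt = dt, t0 = 0,
                                        label = labs[k]))
}

#' Generate a test--retest cohort, optionally writing it to disk
#'
#' Draws \code{n_subjects} subjects for each requested paradigm. With
#' \code{out_dir} set, writes per run a BOLD NIfTI, a motion TSV (BOLD rate)
#' and an ET-CO2 TSV (1 Hz), per subject the ground-truth CVR/delay/label
#' volumes, and a tab-separated \code{manifest.tsv}; output is fully
#' reproducible from the seed.
#'
#' @param n_subjects number of subjects, >= 2 (between-subject repeatability
#'   terms are undefined for a single subject).
#' @param paradigms character vector among "CO2", "BH", "RS".
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @param ... parameter overrides passed to \code{\link{cohortParams}}.
#' @return (invisibly when writing) a list with \code{subjects[[paradigm]][[i]]}
#'   (each a test/retest pair), \code{params[[paradigm]]} and \code{manifest}.
#' @export
generateCohort <- function(n_subjects, paradigms = "CO2", seed = 1L,
                           out_dir = NULL, ...) {
  if (n_subjects < 2)
    stop("n_subjects must be >= 2: between-subject terms of the ",
         "repeatability metrics need at least two subjects")
  paradigms <- match.arg(paradigms, c("CO2", "BH", "RS"), several.ok = TRUE)
  subjects <- list(); params <- list()
  rows <- list()
  for (ip in seq_along(paradigms)) {
    par <- paradigms[ip]
    params[[par]] <- cohortParams(par, ...)
    subjects[[par]] <- lapply(seq_len(n_subjects), function(i) {
      sid <- sprintf("sub-%02d", i)
      generateSubject(params[[par]],
                      subjectID = sid,
                      seed = as.integer((seed + 997L * i + 104729L * ip) %%
                                          .Machine$integer.max))
    })
    names(subjects[[par]]) <- sprintf("sub-%02d", seq_len(n_subjects))
  }
  manifest <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
    for (par in paradigms) for (i in seq_len(n_subjects)) {
      sid <- sprintf("sub-%02d", i)
      pair <- subjects[[par]][[i]]
      stem <- file.path(out_dir, sprintf("%s_%s", sid, tolower(par)))
      truth <- pair$test@truth
      writeVolume(truth@cvr, paste0(stem, "_truth-cvr.nii.gz"),
                  grid = truth@grid)
      writeVolume(truth@delay, paste0(stem, "_truth-delay.nii.gz"),
                  grid = truth@grid)
      writeVolume(truth@labels, paste0(stem, "_truth-labels.nii.gz"),
                  grid = truth@grid)
      for (ses in c("test", "retest")) {
        run <- pair[[ses]]
        bf <- sprintf("%s_%s_bold.nii.gz", stem, ses)
        mf <- sprintf("%s_%s_motion.tsv", stem, ses)
        ef <- sprintf("%s_%s_etco2.tsv", stem, ses)
        writeVolume(run@bold, bf)
        writeTimeseriesTable(run@motion, mf)
        writeTimeseriesTable(list(etco2 = run@etco2), ef)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sid, paradigm = par, session = ses,
          bold = basename(bf), motion = basename(mf), etco2 = basename(ef),
          seed = run@seed)
      }
    }
    manifest <- do.call(rbind, rows)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out <- list(subjects = subjects, params = params, manifest = manifest,
              seed = seed)
  if (is.null(out_dir)) out else invisible(out)
}
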