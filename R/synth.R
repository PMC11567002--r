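# Synthetic ground truth: active zones, event streams, rendered movies,
# and fluorescence traces. All generators are deterministic for a given
# seed and leave the caller's RNG state untouched.

#' Generate a ground-truth active zone
#'
#' Places `nSites` release sites uniformly at random inside an active-zone
#' disk, subject to a minimum inter-site spacing enforced by rejection
#' sampling (all sites are redrawn until every pairwise distance meets the
#' constraint). The default spacing of 60 nm keeps sites resolvable by the
#' 50-nm clustering diameter used downstream.
#'
#' @param nSites number of release sites (>= 1).
#' @param azRadiusNm active-zone disk radius in nm.
#' @param rateProfile per-site release probability per stimulus, length
#'   `nSites`, each in \[0, 1\].
#' @param seed integer RNG seed.
#' @param localizationSigmaNm SD (nm) of the isotropic Gaussian noise
#'   later added to true positions by [sampleEvents()]; default 27 nm.
#' @param minSpacingNm minimum distance between site centers (nm).
#' @param maxTries rejection-sampling attempts before declaring the
#'   spacing infeasible.
#'
#' @return A [GroundTruthAZ-class] object.
#' @examples
#' az <- makeAZ(5, azRadiusNm = 250, rateProfile = rep(0.05, 5), seed = 1)
#' sitePositions(az)
#' @export
makeAZ <- function(nSites, azRadiusNm, rateProfile, seed,
                   localizationSigmaNm = 27, minSpacingNm = 60,
                   maxTries = 5000L) {
  stopifnot(nSites >= 1L, azRadiusNm > 0,
            length(rateProfile) == nSites,
            all(rateProfile >= 0 & rateProfile <= 1),
            minSpacingNm >= 0)
  pos <- .withSeed(seed, {
    found <- NULL
    for (i in seq_len(maxTries)) {
      r <- azRadiusNm * sqrt(stats::runif(nSites))
      th <- 2 * pi * stats::runif(nSites)
      p <- cbind(x = r * cos(th), y = r * sin(th))
      if (nSites == 1L || min(stats::dist(p)) >= minSpacingNm) {
        found <- p
        break
      }
    }
    found
  })
  if (is.null(pos))
    stop(sprintf(paste0("could not place %d sites with minimum spacing ",
                        "%g nm inside a %g-nm-radius AZ after %d attempts; ",
                        "spacing is infeasible"),
                 nSites, minSpacingNm, azRadiusNm, maxTries))
  new("GroundTruthAZ", sitePositions = pos,
      siteRates = as.numeric(rateProfile),
      azRadiusNm = as.numeric(azRadiusNm),
      localizationSigmaNm = as.numeric(localizationSigmaNm))
}

#' Sample a fusion-event stream from a ground-truth AZ
#'
#' For each stimulus in the protocol, every release site releases
#' independently with its per-stimulus probability; at most one event per
#' site per stimulus. Observed positions are the true site positions plus
#' isotropic Gaussian localization noise with SD
#' `localizationSigma(az)`. Stimulus times are mapped to movie frames via
#' the protocol's frame interval, after the baseline frames.
#'
#' @param az a [GroundTruthAZ-class].
#' @param protocol a [StimulusProtocol-class].
#' @param seed integer RNG seed.
#'
#' @return A data.frame with one row per event and columns
#'   `site` (1-based site index), `pulse` (1-based stimulus index),
#'   `time_s` (time from the first movie frame), `frame` (1-based frame
#'   index), `x_true_nm`, `y_true_nm` (true site position) and
#'   `x_nm`, `y_nm` (observed position).
#' @examples
#' az <- makeAZ(3, 250, rep(0.2, 3), seed = 1)
#' ev <- sampleEvents(az, StimulusProtocol(200, 1, 0.05), seed = 2)
#' head(ev)
#' @export
sampleEvents <- function(az, protocol, seed) {
  stopifnot(is(az, "GroundTruthAZ"), is(protocol, "StimulusProtocol"))
  validObject(az); validObject(protocol)
  nP <- nPulses(protocol)
  nS <- nSites(az)
  dt <- frameInterval(protocol)
  t0 <- nBaselineFrames(protocol) * dt
  .withSeed(seed, {
    if (nP == 0L) {
      rel <- matrix(FALSE, 0L, nS)
    } else {
      rel <- matrix(stats::runif(nP * nS), nP, nS) <
        matrix(rep(siteRates(az), each = nP), nP, nS)
    }
    idx <- which(rel, arr.ind = TRUE)
    # time order: pulse-major, then site
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    pulse <- idx[, 1]; site <- idx[, 2]
    tEvent <- t0 + (pulse - 1) / stimulusFrequency(protocol)
    frame <- as.integer(floor(tEvent / dt)) + 1L
    pos <- sitePositions(az)[site, , drop = FALSE]
    nE <- length(site)
    noise <- matrix(stats::rnorm(2L * nE, sd = localizationSigma(az)),
                    ncol = 2L)
    data.frame(
      site = as.integer(site),
      pulse = as.integer(pulse),
      time_s = tEvent,
      frame = frame,
      x_true_nm = pos[, 1],
      y_true_nm = pos[, 2],
      x_nm = pos[, 1] + noise[, 1],
      y_nm = pos[, 2] + noise[, 2]
    )
  })
}

# Expected pixel values for point emitters in one frame: integrated 2-d
# Gaussian PSF (pixel-area-averaged) plus flat background, photon units.
# Positions in nm in the movie coordinate frame (origin at center of
# pixel (1,1)).
.expectedFrame <- function(xNm, yNm, photons, psfSigmaNm, background,
                           pixelSizeNm, nRow, nCol) {
  img <- matrix(background, nRow, nCol)
  if (length(xNm) == 0L) return(img)
  s <- psfSigmaNm / pixelSizeNm
  colsPx <- seq_len(nCol) - 1  # pixel-center x in px units
  rowsPx <- seq_len(nRow) - 1
  for (i in seq_along(xNm)) {
    xp <- xNm[i] / pixelSizeNm
    yp <- yNm[i] / pixelSizeNm
    gx <- stats::pnorm((colsPx + 0.5 - xp) / s) -
      stats::pnorm((colsPx - 0.5 - xp) / s)
    gy <- stats::pnorm((rowsPx + 0.5 - yp) / s) -
      stats::pnorm((rowsPx - 0.5 - yp) / s)
    img <- img + photons[i] * (gy %o% gx)
  }
  img
}

#' Render an event stream as a near-TIRF movie
#'
#' Renders each event as an integrated (pixel-area-averaged) 2-d Gaussian
#' spot at its observed position in its frame, adds a flat background, and
#' applies Poisson photon noise to signal plus background. Frames without
#' events contain background only.
#'
#' @param events event data.frame from [sampleEvents()], or any
#'   data.frame with columns `frame`, `x_nm`, `y_nm`.
#' @param psfSigmaNm PSF Gaussian SD in nm.
#' @param photonsPerEvent expected photons collected per event.
#' @param background expected background photons per pixel per frame.
#' @param pixelSizeNm pixel size in nm (default 87, a 150x objective with
#'   13-um camera pixels).
#' @param shape integer(2), movie rows and columns.
#' @param nFrames number of frames; defaults to the largest event frame.
#' @param frameIntervalS frame interval in seconds (default 0.05).
#' @param seed integer RNG seed for the Poisson noise.
#' @param noise logical; `FALSE` renders the noiseless expectation.
#' @param outOfBounds `"clip"` drops (with a warning) events outside the
#'   field of view; `"error"` aborts.
#'
#' @return A [Movie-class] on the photon-count scale.
#' @examples
#' az <- makeAZ(2, 200, c(0.3, 0.3), seed = 1)
#' ev <- sampleEvents(az, StimulusProtocol(20, 1, 0.05), seed = 2)
#' ev$x_nm <- ev$x_nm + 700; ev$y_nm <- ev$y_nm + 700  # center in FOV
#' mv <- renderMovie(ev, psfSigmaNm = 130, photonsPerEvent = 500,
#'                   background = 5, shape = c(16, 16), seed = 3)
#' mv
#' @export
renderMovie <- function(events, psfSigmaNm, photonsPerEvent, background = 0,
                        pixelSizeNm = 87, shape = c(32L, 32L),
                        nFrames = NULL, frameIntervalS = 0.05, seed = NULL,
                        noise = TRUE, outOfBounds = c("clip", "error")) {
  stopifnot(psfSigmaNm > 0, photonsPerEvent > 0, background >= 0,
            all(c("frame", "x_nm", "y_nm") %in% names(events)))
  outOfBounds <- match.arg(outOfBounds)
  nRow <- as.integer(shape[1]); nCol <- as.integer(shape[2])
  if (is.null(nFrames))
    nFrames <- if (nrow(events)) max(events$frame) else 1L
  nFrames <- as.integer(nFrames)

  xlim <- c(-0.5, nCol - 0.5) * pixelSizeNm
  ylim <- c(-0.5, nRow - 0.5) * pixelSizeNm
  oob <- events$x_nm < xlim[1] | events$x_nm > xlim[2] |
    events$y_nm < ylim[1] | events$y_nm > ylim[2] |
    events$frame < 1L | events$frame > nFrames
  if (any(oob)) {
    if (outOfBounds == "error")
      stop(sprintf("%d event(s) fall outside the field of view or frame range",
                   sum(oob)))
    warning(sprintf("clipping %d event(s) outside the field of view", sum(oob)))
    events <- events[!oob, , drop = FALSE]
  }

  arr <- array(0, dim = c(nRow, nCol, nFrames))
  byFrame <- split(seq_len(nrow(events)), events$frame)
  bgOnly <- .expectedFrame(numeric(0), numeric(0), numeric(0), psfSigmaNm,
                           background, pixelSizeNm, nRow, nCol)
  for (t in seq_len(nFrames)) {
    rows <- byFrame[[as.character(t)]]
    if (is.null(rows)) {
      arr[, , t] <- bgOnly
    } else {
      arr[, , t] <- .expectedFrame(events$x_nm[rows], events$y_nm[rows],
                                   rep(photonsPerEvent, length(rows)),
                                   psfSigmaNm, background, pixelSizeNm,
                                   nRow, nCol)
    }
  }
  if (noise)
    arr <- .withSeed(seed, array(stats::rpois(length(arr), arr), dim = dim(arr)))
  Movie(arr, pixelSizeNm = pixelSizeNm, frameIntervalS = frameIntervalS)
}

#' Simulate a vGLUT1-pHluorin train response
#'
#' Produces a fluorescence trace with the canonical pHluorin shape:
#' constant baseline `f0` over the baseline frames, a linear rise to
#' `f0 + deltaFMax` across the stimulus window, and a single-exponential
#' return `f0 + deltaFMax * exp(-t/tau)` after the last stimulus frame,
#' with additive Gaussian noise.
#'
#' @param gt a [GroundTruthTrace-class].
#' @param protocol a [StimulusProtocol-class]; the stimulus window spans
#'   `ceiling(nPulses/frequency/frameInterval)` frames after the baseline.
#' @param seed integer RNG seed.
#' @param nPostFrames frames recorded after the stimulus; default covers
#'   5 time constants.
#'
#' @return A [Trace-class] with baseline and stimulus windows annotated.
#' @examples
#' gt <- GroundTruthTrace(f0 = 100, deltaFMax = 50, tauEndoS = 15)
#' tr <- simulatePhluorinTrace(gt, StimulusProtocol(100, 10, 0.5), seed = 1)
#' tr
#' @export
simulatePhluorinTrace <- function(gt, protocol, seed = NULL,
                                  nPostFrames = NULL) {
  stopifnot(is(gt, "GroundTruthTrace"), is(protocol, "StimulusProtocol"))
  validObject(gt); validObject(protocol)
  dt <- frameInterval(protocol)
  nB <- nBaselineFrames(protocol)
  stimDur <- nPulses(protocol) / stimulusFrequency(protocol)
  nStim <- max(1L, as.integer(ceiling(stimDur / dt)))
  if (is.null(nPostFrames))
    nPostFrames <- as.integer(ceiling(5 * gt@tauEndoS / dt))
  nPostFrames <- max(5L, as.integer(nPostFrames))

  base <- rep(gt@f0, nB)
  rise <- gt@f0 + gt@deltaFMax * seq_len(nStim) / nStim
  tPost <- seq_len(nPostFrames) * dt
  decay <- gt@f0 + gt@deltaFMax * exp(-tPost / gt@tauEndoS)
  v <- c(base, rise, decay)
  if (gt@noiseSd > 0)
    v <- .withSeed(seed, v + stats::rnorm(length(v), sd = gt@noiseSd))
  Trace(v, frameIntervalS = dt,
        baselineWindow = c(1L, max(1L, nB)),
        stimulusWindow = c(nB + 1L, nB + nStim))
}

#' Simulate a step response of a perfused biosensor
#'
#' Models a mitochondrial pyruvate-sensor experiment: perfusion switches
#' the analyte on at `onFrame` and off at `offFrame`; fluorescence
#' approaches the plateau mono-exponentially while the analyte is present
#' and returns to baseline mono-exponentially after washout.
#'
#' @param baselineF baseline fluorescence (a.u., > 0).
#' @param plateauDff asymptotic response amplitude as dF/F0 (unitless).
#' @param onFrame,offFrame 1-based frames of analyte onset and washout
#'   (`onFrame < offFrame`).
#' @param kineticTauS sensor/equilibration time constant in seconds.
#' @param noiseSd SD of additive Gaussian noise (a.u.).
#' @param frameIntervalS frame interval in seconds (default 0.5).
#' @param nFrames total trace length in frames.
#' @param seed integer RNG seed.
#'
#' @return A [Trace-class]; the baseline window is the pre-onset segment
#'   and the "stimulus" window is the perfusion window
#'   `onFrame..offFrame`.
#' @examples
#' tr <- simulateStepSensorTrace(100, 0.6, onFrame = 30, offFrame = 150,
#'                               kineticTauS = 5, noiseSd = 0, nFrames = 240)
#' max(traceValues(tr))
#' @export
simulateStepSensorTrace <- function(baselineF, plateauDff, onFrame, offFrame,
                                    kineticTauS, noiseSd = 0,
                                    frameIntervalS = 0.5, nFrames, seed = NULL) {
  stopifnot(baselineF > 0, onFrame < offFrame, onFrame >= 2L,
            kineticTauS > 0, noiseSd >= 0, nFrames >= offFrame)
  t <- (seq_len(nFrames) - 1) * frameIntervalS
  tOn <- (onFrame - 1) * frameIntervalS
  tOff <- (offFrame - 1) * frameIntervalS
  dff <- numeric(nFrames)
  on <- t >= tOn & t <= tOff
  dff[on] <- plateauDff * (1 - exp(-(t[on] - tOn) / kineticTauS))
  dffAtOff <- plateauDff * (1 - exp(-(tOff - tOn) / kineticTauS))
  post <- t > tOff
  dff[post] <- dffAtOff * exp(-(t[post] - tOff) / kineticTauS)
  v <- baselineF * (1 + dff)
  if (noiseSd > 0)
    v <- .withSeed(seed, v + stats::rnorm(nFrames, sd = noiseSd))
  Trace(v, frameIntervalS = frameIntervalS,
        baselineWindow = c(1L, onFrame - 1L),
        stimulusWindow = c(as.integer(onFrame), as.integer(offFrame)))
}
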