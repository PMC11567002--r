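# Fluorescence-trace quantification: dF/F0, release probability, exo- and
# endocytosis rates, endocytic time constant, fractional retrieval block,
# sensor peak responses and channel ratios.

#' Normalize a trace to dF/F0
#'
#' F0 is the mean over the baseline window; the output is (F - F0) / F0.
#' A non-positive F0 signals a bad ROI or background subtraction and is
#' rejected.
#'
#' @param trace a [Trace-class].
#'
#' @return A [Trace-class] whose values are dF/F0, windows preserved.
#' @examples
#' tr <- Trace(c(rep(100, 10), 150, 140), 0.5, c(1, 10), c(11, 12))
#' max(traceValues(normalizeDFF(tr)))   # 0.5
#' @export
normalizeDFF <- function(trace) {
  stopifnot(is(trace, "Trace"))
  validObject(trace)
  bw <- baselineWindow(trace)
  f0 <- mean(traceValues(trace)[bw[1]:bw[2]])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean F0 must be positive; check ROI and background subtraction")
  Trace((traceValues(trace) - f0) / f0, frameInterval(trace),
        baselineWindow(trace), stimulusWindow(trace))
}

#' Release probability
#'
#' Pr = detected events / stimuli delivered, per synapse. Values above 1
#' are possible at multi-site AZs (more than one event per AP) and are
#' flagged rather than rejected.
#'
#' @param nEvents number of detected fusion events.
#' @param protocol a [StimulusProtocol-class] with `nPulses > 0`.
#'
#' @return Pr (numeric); attribute `"flagged"` is TRUE when Pr > 1.
#' @examples
#' releaseProbability(50, StimulusProtocol(200, 1, 0.05))   # 0.25
#' @export
releaseProbability <- function(nEvents, protocol) {
  stopifnot(is(protocol, "StimulusProtocol"), nPulses(protocol) > 0L,
            nEvents >= 0)
  pr <- nEvents / nPulses(protocol)
  attr(pr, "flagged") <- pr > 1
  pr
}

#' Exocytosis and endocytosis rates from a train response
#'
#' Least-squares line slopes of a normalized trace over the rise segment
#' (the stimulus window) and over an early post-stimulus decay segment,
#' in dF/F0 per second. For a decay window much shorter than the
#' endocytic time constant the decay slope approximates the initial
#' derivative -dFmax/tau.
#'
#' @param dff a dF/F0 [Trace-class] (see [normalizeDFF()]).
#' @param decayFrames length of the early-decay segment in frames;
#'   defaults to the stimulus-window length (at least 3).
#'
#' @return list with `riseRate`, `decayRate` (dF/F0 per s) and the frame
#'   windows used.
#' @export
exoEndoRates <- function(dff, decayFrames = NULL) {
  stopifnot(is(dff, "Trace"))
  sw <- stimulusWindow(dff)
  v <- traceValues(dff)
  dt <- frameInterval(dff)
  if (sw[2] - sw[1] + 1L < 3L) stop("stimulus window must span >= 3 frames")
  if (is.null(decayFrames)) decayFrames <- max(3L, sw[2] - sw[1] + 1L)
  decayFrames <- as.integer(decayFrames)
  dw <- c(sw[2] + 1L, min(length(v), sw[2] + decayFrames))
  if (dw[2] - dw[1] + 1L < 3L) stop("post-stimulus segment must span >= 3 frames")
  riseIdx <- sw[1]:sw[2]
  decayIdx <- dw[1]:dw[2]
  riseRate <- unname(stats::coef(stats::lm(v[riseIdx] ~ I(riseIdx * dt)))[2])
  decayRate <- unname(stats::coef(stats::lm(v[decayIdx] ~ I(decayIdx * dt)))[2])
  list(riseRate = riseRate, decayRate = decayRate,
       riseWindow = sw, decayWindow = dw)
}

#' Fit the endocytic time constant
#'
#' Nonlinear least-squares fit of the post-stimulus segment of a dF/F0
#' trace to `fInf + deltaFMax * exp(-(t - tEnd)/tau)`, where tEnd is the
#' time of the last stimulus frame. With `anchored = TRUE` (default) the
#' curve is anchored to the measured end-of-stimulation value, so only
#' fInf and tau are free; otherwise the amplitude is free as well. Tau is
#' bounded by 10x the post-stimulus segment length; a boundary-pinned or
#' failed fit sets `converged` to FALSE. A non-decaying segment is an
#' explicit failure.
#'
#' @param dff a dF/F0 [Trace-class] with at least 5 post-stimulus frames.
#' @param anchored anchor the amplitude to the end-of-stimulation dF
#'   (default TRUE).
#'
#' @return An [EndoFit-class].
#' @export
fitEndocyticTau <- function(dff, anchored = TRUE) {
  stopifnot(is(dff, "Trace"))
  v <- traceValues(dff)
  sw <- stimulusWindow(dff)
  dt <- frameInterval(dff)
  postIdx <- (sw[2] + 1L):length(v)
  if (length(postIdx) < 5L)
    stop("need >= 5 post-stimulus frames to fit the endocytic decay")
  fEnd <- v[sw[2]]
  y <- v[postIdx]
  t <- (postIdx - sw[2]) * dt
  segLen <- max(t)
  slope <- unname(stats::coef(stats::lm(y ~ t))[2])
  if (slope >= 0 || fEnd <= min(y))
    return(new("EndoFit", tauS = NA_real_, deltaFMax = NA_real_,
               fInf = NA_real_, residualNorm = NA_real_, converged = FALSE,
               message = "post-stimulus segment is non-decaying"))
  tauMax <- 10 * segLen
  # crude initial tau: time to reach halfway between fEnd and the tail
  tail <- mean(y[max(1L, length(y) - 2L):length(y)])
  half <- tail + (fEnd - tail) / 2
  below <- which(y <= half)
  tau0 <- if (length(below)) max(t[below[1]] / log(2), dt) else segLen / 2
  model <- if (anchored) {
    function(p) p[1] + (fEnd - p[1]) * exp(-t / p[2]) - y
  } else {
    function(p) p[1] + p[3] * exp(-t / p[2]) - y
  }
  par0 <- if (anchored) c(fInf = tail, tau = tau0)
          else c(fInf = tail, tau = tau0, dF = fEnd - tail)
  lower <- if (anchored) c(-Inf, 1e-9) else c(-Inf, 1e-9, 0)
  upper <- if (anchored) c(Inf, tauMax) else c(Inf, tauMax, Inf)
  fit <- try(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = model,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4))
    return(new("EndoFit", tauS = NA_real_, deltaFMax = NA_real_,
               fInf = NA_real_, residualNorm = NA_real_, converged = FALSE,
               message = "optimizer failed"))
  p <- fit$par
  tau <- unname(p["tau"])
  fInf <- unname(p["fInf"])
  dF <- if (anchored) fEnd - fInf else unname(p["dF"])
  pinned <- tau >= tauMax * (1 - 1e-6) || tau <= 2e-9
  new("EndoFit", tauS = tau, deltaFMax = dF, fInf = fInf,
      residualNorm = sum(fit$fvec^2), converged = !pinned,
      message = if (pinned) "tau pinned at bound" else "ok")
}

#' Fractional retrieval block
#'
#' The proportion of dF remaining two control time-constants after the
#' end of stimulation: dF at `tEnd + 2*controlTauS` (linearly
#' interpolated between frames) divided by dF at the end of stimulation
#' (dFmax). The control tau is the mean endocytic time constant of the
#' designated control group and is applied to every group. For an ideal
#' exponential with time constant tau the block equals
#' `exp(-2*controlTau/tau)`: ~0.135 for tau equal to the control, 1 for
#' fully blocked retrieval.
#'
#' @param dff a dF/F0 [Trace-class].
#' @param controlTauS control-group mean endocytic time constant (s).
#' @param reference `"baseline"` (default) measures dF from the baseline
#'   (dF/F0 = 0); `"finf"` measures from the trace's final plateau, for
#'   traces that do not return to baseline for reasons other than a
#'   retrieval block.
#'
#' @return The fractional retrieval block (numeric).
#' @examples
#' gt <- GroundTruthTrace(100, 50, tauEndoS = 10)
#' tr <- simulatePhluorinTrace(gt, StimulusProtocol(100, 10, 0.5))
#' fractionalRetrievalBlock(normalizeDFF(tr), controlTauS = 10)  # ~ exp(-2)
#' @export
fractionalRetrievalBlock <- function(dff, controlTauS,
                                     reference = c("baseline", "finf")) {
  stopifnot(is(dff, "Trace"), controlTauS > 0)
  reference <- match.arg(reference)
  v <- traceValues(dff)
  sw <- stimulusWindow(dff)
  dt <- frameInterval(dff)
  tTarget <- 2 * controlTauS
  tPost <- (seq_along(v) - sw[2]) * dt
  if (max(tPost) < tTarget)
    stop(sprintf(paste0("trace ends %.3g s after stimulation but 2*controlTau ",
                        "= %.3g s is required"), max(tPost), tTarget))
  ref <- if (reference == "baseline") 0 else v[length(v)]
  dFmax <- v[sw[2]] - ref
  if (dFmax <= 0)
    stop("dF at the end of stimulation must be positive")
  dF2tau <- stats::approx(tPost, v, xout = tTarget)$y - ref
  dF2tau / dFmax
}

#' Peak dF/F0 response in a window
#'
#' Maximum of the (optionally smoothed) dF/F0 values inside the response
#' window. Smoothing with a short moving mean (default 3 frames) removes
#' the upward bias that raw maxima of noisy traces carry.
#'
#' @param dff a dF/F0 [Trace-class].
#' @param window integer(2) frame range to search; defaults to the
#'   stimulus window.
#' @param smoothFrames moving-mean width in frames; 1 disables smoothing.
#'
#' @return Peak dF/F0; attribute `"flagged"` is TRUE when the peak is
#'   negative.
#' @export
peakResponse <- function(dff, window = NULL, smoothFrames = 3L) {
  stopifnot(is(dff, "Trace"), smoothFrames >= 1L)
  v <- traceValues(dff)
  if (is.null(window)) window <- stimulusWindow(dff)
  stopifnot(length(window) == 2L, window[1] >= 1L,
            window[2] <= length(v), window[1] <= window[2])
  sm <- .movingMean(v, as.integer(smoothFrames))
  pk <- max(sm[window[1]:window[2]])
  attr(pk, "flagged") <- pk < 0
  pk
}

#' Frame-wise ratio of two fluorescence channels
#'
#' Used for ratiometric sensors reported as, e.g., the GFP / far-red
#' intensity ratio.
#'
#' @param numerator,denominator numeric vectors of equal length, or
#'   [Trace-class] objects; denominator values must be positive.
#' @param window optional integer(2) frame range for the mean.
#'
#' @return list with `ratio` (per frame) and `mean` over the window.
#' @export
channelRatio <- function(numerator, denominator, window = NULL) {
  if (is(numerator, "Trace")) numerator <- traceValues(numerator)
  if (is(denominator, "Trace")) denominator <- traceValues(denominator)
  stopifnot(length(numerator) == length(denominator),
            all(denominator > 0))
  r <- numerator / denominator
  if (is.null(window)) window <- c(1L, length(r))
  list(ratio = r, mean = mean(r[window[1]:window[2]]))
}
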