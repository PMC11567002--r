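# Trace quantification: dF/F0, Pr, rates, tau, retrieval block, peaks.

protoTrain <- StimulusProtocol(100, 10, 0.5)   # 100 AP at 10 Hz, 2 Hz imaging

test_that("dF/F0 normalization follows the baseline definition", {
  tr <- Trace(c(rep(100, 10), 150, 140), 0.5, c(1, 10), c(11, 12))
  d <- normalizeDFF(tr)
  expect_equal(max(traceValues(d)), 0.5)
  expect_equal(traceValues(d)[1:10], rep(0, 10))

  # constant trace: all zeros
  cst <- Trace(rep(80, 20), 0.5, c(1, 5), c(6, 10))
  expect_true(all(traceValues(normalizeDFF(cst)) == 0))

  # non-positive baseline is rejected (guards double-normalization)
  bad <- Trace(c(rep(0, 5), 1, 2, 3), 0.5, c(1, 5), c(6, 8))
  expect_error(normalizeDFF(bad), "positive")

  # round trip with the step generator
  st <- simulateStepSensorTrace(120, 0.8, 30, 400, 5, 0, nFrames = 420)
  expect_equal(max(traceValues(normalizeDFF(st))), 0.8, tolerance = 1e-6)
})

test_that("release probability is events per stimulus", {
  expect_equal(as.numeric(releaseProbability(50, StimulusProtocol(200, 1, 0.05))), 0.25)
  expect_equal(as.numeric(releaseProbability(0, StimulusProtocol(200, 1, 0.05))), 0)
  over <- releaseProbability(250, StimulusProtocol(200, 1, 0.05))
  expect_true(attr(over, "flagged"))

  # generator round trip: mean Pr across seeds matches the site rate
  az <- makeAZ(1, 250, 0.2, seed = 8)
  proto <- StimulusProtocol(200, 1, 0.05)
  prs <- vapply(1:500, function(s) {
    as.numeric(releaseProbability(nrow(sampleEvents(az, proto, seed = s)), proto))
  }, numeric(1))
  expect_lt(abs(mean(prs) - 0.2), 3 * sqrt(0.2 * 0.8 / 200 / 500))
})

test_that("rise and decay rates recover linear and exponential slopes", {
  # exact ramp at 0.1/s during the stimulus
  v <- c(rep(0, 30), seq(0.05, 0.5, by = 0.05), rep(0.5, 20))
  tr <- Trace(v, 0.5, c(1, 30), c(31, 40))
  r <- exoEndoRates(tr)
  expect_equal(r$riseRate, 0.1, tolerance = 1e-9)
  expect_equal(r$decayRate, 0, tolerance = 1e-9)

  # early-window slope of an exponential matches -dFmax/tau for a short
  # window
  gt <- GroundTruthTrace(100, 80, tauEndoS = 40)
  d <- normalizeDFF(simulatePhluorinTrace(gt, protoTrain))
  r2 <- exoEndoRates(d, decayFrames = 4L)   # 2 s window << tau = 40 s
  expect_lt(abs(r2$decayRate - (-0.8 / 40)) / (0.8 / 40), 0.05)
})

test_that("endocytic tau is recovered exactly on noiseless traces", {
  gt <- GroundTruthTrace(100, 50, tauEndoS = 10)
  fit <- fitEndocyticTau(normalizeDFF(simulatePhluorinTrace(gt, protoTrain)))
  expect_true(hasConverged(fit))
  expect_lt(abs(endoTau(fit) - 10) / 10, 1e-6)

  # free-amplitude variant agrees on the exact model class
  fit2 <- fitEndocyticTau(normalizeDFF(simulatePhluorinTrace(gt, protoTrain)),
                          anchored = FALSE)
  expect_lt(abs(endoTau(fit2) - 10) / 10, 1e-5)

  # flat post-stimulus trace: explicit non-decaying failure
  flat <- Trace(c(rep(1, 10), seq(1, 2, length.out = 10), rep(2, 10)),
                0.5, c(1, 10), c(11, 20))
  f3 <- fitEndocyticTau(flat)
  expect_false(hasConverged(f3))
  expect_match(f3@message, "non-decaying")
})

test_that("tau recovery under 5% noise has small median error", {
  gt <- GroundTruthTrace(100, 50, tauEndoS = 15, noiseSd = 0.05 * 50)
  errs <- vapply(1:100, function(s) {
    fit <- fitEndocyticTau(normalizeDFF(
      simulatePhluorinTrace(gt, protoTrain, seed = s)))
    if (hasConverged(fit)) abs(endoTau(fit) - 15) / 15 else NA_real_
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 0.10)
})

test_that("fractional retrieval block matches its closed forms", {
  proto <- protoTrain
  mk <- function(tau) normalizeDFF(simulatePhluorinTrace(
    GroundTruthTrace(100, 50, tauEndoS = tau), proto,
    nPostFrames = ceiling(8 * 40 / 0.5)))
  ctrl <- 10
  # tau equal to control tau: exp(-2)
  expect_equal(fractionalRetrievalBlock(mk(10), ctrl), exp(-2),
               tolerance = 1e-6)
  # general closed form exp(-2 tau_c / tau)
  for (ratio in c(0.5, 2, 3))
    expect_equal(fractionalRetrievalBlock(mk(10 * ratio), ctrl),
                 exp(-2 / ratio), tolerance = 1e-6)

  # no endocytosis: flat after stimulus -> block 1
  v <- c(rep(100, 30), seq(100, 150, length.out = 10), rep(150, 100))
  tr <- normalizeDFF(Trace(v, 0.5, c(1, 30), c(31, 40)))
  expect_equal(fractionalRetrievalBlock(tr, ctrl), 1)

  # too-short trace names the required duration
  short <- normalizeDFF(Trace(c(rep(100, 30), 150, 149, 148, 147, 146),
                              0.5, c(1, 30), c(31, 31)))
  expect_error(fractionalRetrievalBlock(short, ctrl), "required")
})

test_that("the retrieval block is scale-invariant and monotone in tau", {
  proto <- protoTrain
  gt <- GroundTruthTrace(100, 50, tauEndoS = 20)
  tr <- simulatePhluorinTrace(gt, proto)
  b1 <- fractionalRetrievalBlock(normalizeDFF(tr), 10)
  scaled <- Trace(traceValues(tr) * 3.7, frameInterval(tr),
                  baselineWindow(tr), stimulusWindow(tr))
  b2 <- fractionalRetrievalBlock(normalizeDFF(scaled), 10)
  expect_equal(b1, b2, tolerance = 1e-12)

  taus <- c(5, 10, 20, 40)
  blocks <- vapply(taus, function(tau) {
    fractionalRetrievalBlock(normalizeDFF(simulatePhluorinTrace(
      GroundTruthTrace(100, 50, tauEndoS = tau), proto,
      nPostFrames = 400)), 10)
  }, numeric(1))
  expect_true(all(diff(blocks) > 0))
  expect_equal(blocks, exp(-2 * 10 / taus), tolerance = 1e-6)
})

test_that("peak responses are extracted with bounded smoothing bias", {
  st <- simulateStepSensorTrace(100, 0.6, 30, 300, 4, 0, nFrames = 360)
  d <- normalizeDFF(st)
  expect_equal(as.numeric(peakResponse(d)), 0.6, tolerance = 1e-4)

  # negative response is returned and flagged
  neg <- Trace(c(rep(100, 10), rep(80, 10)), 0.5, c(1, 10), c(11, 20))
  pk <- peakResponse(normalizeDFF(neg))
  expect_lt(as.numeric(pk), 0)
  expect_true(attr(pk, "flagged"))

  # at SNR ~20 the smoothed peak measured on the steady-state plateau
  # has small bias; the raw peak is biased upward and larger (max of
  # noise)
  noise <- 0.6 / 20
  win <- c(292L, 297L)   # plateau window just before washout
  sm <- raw <- numeric(100)
  for (s in 1:100) {
    stn <- simulateStepSensorTrace(100, 0.6, 30, 300, 4, noise * 100,
                                   nFrames = 360, seed = s)
    dn <- normalizeDFF(stn)
    sm[s] <- peakResponse(dn, window = win, smoothFrames = 7L)
    raw[s] <- peakResponse(dn, window = win, smoothFrames = 1L)
  }
  expect_lt(abs(mean(sm) - 0.6) / 0.6, 0.02)
  expect_gt(mean(raw) - 0.6, 0)
  expect_gt(mean(raw), mean(sm))
})

test_that("channel ratios behave multiplicatively", {
  a <- c(1, 2, 3, 4)
  expect_equal(channelRatio(a, a)$ratio, rep(1, 4))
  expect_equal(channelRatio(2 * a, a)$mean, 2)

  # multiplicative log-normal noise on both channels: E[num/den] =
  # exp(sigma_d^2) for independent log-normal factors (analytic)
  set.seed(77)
  sdl <- 0.1
  n <- 20000
  num <- 100 * exp(rnorm(n, 0, sdl) - sdl^2 / 2)
  den <- 100 * exp(rnorm(n, 0, sdl) - sdl^2 / 2)
  expected <- exp(sdl^2)
  got <- channelRatio(num, den)$mean
  expect_lt(abs(got - expected) / expected, 0.01)
})
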