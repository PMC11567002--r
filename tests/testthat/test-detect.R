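# Candidate detection and sub-pixel mixture-model localization.

test_that("constant movies yield no candidates", {
  mv <- Movie(array(0, dim = c(21, 21, 5)), 87, 0.05)
  expect_identical(nrow(detectCandidates(mv)), 0L)
  mv2 <- Movie(array(7, dim = c(21, 21, 5)), 87, 0.05)
  expect_identical(nrow(detectCandidates(mv2)), 0L)
})

test_that("a noiseless spot gives exactly one candidate at its pixel", {
  mv <- singleSpotMovie(870, 870, photons = 1000, background = 5)
  cand <- detectCandidates(mv)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$frame, 2L)
  expect_identical(cand$row, 11L)   # y = 870 nm -> row 11 at 87 nm/px
  expect_identical(cand$col, 11L)
})

test_that("detection at SNR ~10 has high recall and few false positives", {
  set.seed(42)
  nEv <- 100
  pos <- cbind(runif(nEv, 6, 26), runif(nEv, 6, 26)) * 87
  ev <- data.frame(frame = seq(2, by = 2, length.out = nEv),
                   x_nm = pos[, 1], y_nm = pos[, 2])
  mv <- renderMovie(ev, 130, photonsPerEvent = 500, background = 10,
                    shape = c(32, 32), nFrames = 201, seed = 7)
  cand <- detectCandidates(mv)
  hit <- vapply(seq_len(nEv), function(i) {
    cc <- cand[cand$frame == ev$frame[i], , drop = FALSE]
    if (!nrow(cc)) return(FALSE)
    any(sqrt(((cc$col - 1) * 87 - ev$x_nm[i])^2 +
             ((cc$row - 1) * 87 - ev$y_nm[i])^2) <= 2 * 87)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  bgFrames <- setdiff(seq(3, 201, 2), ev$frame)  # background-only frames
  expect_lte(sum(cand$frame %in% bgFrames), 2)
})

test_that("localization is exact on noiseless symmetric spots", {
  # spot at the center of pixel (11, 11): (870, 870) nm
  mv <- singleSpotMovie(870, 870, 1000, 5)
  f <- fitSpots(mv, data.frame(frame = 2L, row = 11L, col = 11L, value = 1))
  expect_identical(nrow(f), 1L)
  expect_lt(abs(f$x_nm - 870) / 87, 1e-6)
  expect_lt(abs(f$y_nm - 870) / 87, 1e-6)
  # sub-pixel position, still noiseless: recovered to numerical accuracy
  mv2 <- singleSpotMovie(901.3, 845.2, 1000, 5)
  f2 <- fitSpots(mv2, data.frame(frame = 2L, row = 11L, col = 11L, value = 1))
  expect_lt(abs(f2$x_nm - 901.3), 1e-3)
  expect_lt(abs(f2$y_nm - 845.2), 1e-3)
})

test_that("reported precision is self-consistent with Monte-Carlo scatter", {
  cand <- data.frame(frame = 2L, row = 11L, col = 11L, value = 1)
  cfg <- detectionConfig(maxKernels = 1L)
  n <- 1000
  res <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    mv <- singleSpotMovie(870, 870, 500, 10, noise = TRUE, seed = i)
    f <- fitSpots(mv, cand, cfg)
    if (nrow(f) == 1L) res[i, ] <- c(f$x_nm, f$precision_nm)
  }
  ok <- !is.na(res[, 1])
  expect_gte(mean(ok), 0.95)
  empSD <- sd(res[ok, 1])
  expect_lt(abs(empSD - mean(res[ok, 2])) / empSD, 0.15)
})

test_that("empirical precision degrades monotonically with fewer photons", {
  cand <- data.frame(frame = 2L, row = 11L, col = 11L, value = 1)
  cfg <- detectionConfig(maxKernels = 1L)
  sdAt <- function(photons) {
    x <- vapply(1:120, function(i) {
      mv <- singleSpotMovie(870, 870, photons, 10, noise = TRUE, seed = i)
      f <- fitSpots(mv, cand, cfg)
      if (nrow(f) == 1L) f$x_nm else NA_real_
    }, numeric(1))
    sd(x, na.rm = TRUE)
  }
  s <- vapply(c(2000, 500, 150), sdAt, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("re-detected positions respect the information-limit oracle", {
  # rendered then re-fit spots: RMSE bounded below by the CRLB and
  # within the efficiency range of least squares
  cand <- data.frame(frame = 2L, row = 11L, col = 11L, value = 1)
  cfg <- detectionConfig(maxKernels = 1L)
  x <- vapply(1:200, function(i) {
    mv <- singleSpotMovie(870, 870, 800, 10, noise = TRUE, seed = 3000 + i)
    f <- fitSpots(mv, cand, cfg)
    if (nrow(f) == 1L) f$x_nm else NA_real_
  }, numeric(1))
  rmse <- sqrt(mean((x[!is.na(x)] - 870)^2))
  crlb <- crlbCenterNm(800, 10, 130, 87, 5)
  expect_gte(rmse, 0.85 * crlb)
  expect_lte(rmse, 1.8 * crlb)
})

test_that("two spots 3 sigma apart are resolved as a two-kernel mixture", {
  sep <- 3 * 130
  ctr <- 10 * 87
  truth <- data.frame(frame = 2L, x_nm = c(ctr - sep / 2, ctr + sep / 2),
                      y_nm = c(ctr, ctr))
  mv <- renderMovie(truth, 130, 1500, 10, shape = c(21, 21), nFrames = 2,
                    seed = 3)
  cand <- detectCandidates(mv)
  f <- fitSpots(mv, cand)
  expect_identical(nrow(f), 2L)
  expect_true(all(f$n_kernels == 2L))
  f <- f[order(f$x_nm), ]
  expect_lt(max(abs(f$x_nm - truth$x_nm)) / 87, 0.25)
  expect_lt(max(abs(f$y_nm - truth$y_nm)) / 87, 0.25)

  # brute-force two-kernel grid-search oracle on the window of the first
  # candidate (row 11, col 9 -> rows 6:16, cols 4:14): the fit must be at
  # least as good (in RSS) as the best grid placement around the truth
  win <- frames(mv)[6:16, 4:14, 2]
  rowsPx <- 5:15; colsPx <- 3:13
  g <- function(u, c0, s) pnorm((u + 0.5 - c0) / s) - pnorm((u - 0.5 - c0) / s)
  s0 <- 130 / 87
  offs <- seq(-0.5, 0.5, by = 0.125)
  bestRss <- Inf
  x1t <- truth$x_nm[1] / 87; x2t <- truth$x_nm[2] / 87; yt <- truth$y_nm[1] / 87
  for (dx1 in offs) for (dx2 in offs) {
    g1 <- g(rowsPx, yt, s0) %o% g(colsPx, x1t + dx1, s0)
    g2 <- g(rowsPx, yt, s0) %o% g(colsPx, x2t + dx2, s0)
    X <- cbind(1, as.vector(g1), as.vector(g2))
    rss <- sum(stats::lm.fit(X, as.vector(win))$residuals^2)
    if (rss < bestRss) bestRss <- rss
  }
  # RSS of the package fit on the same window, from its fitted parameters
  ff <- fitSpots(mv, cand[1, , drop = FALSE])
  expect_identical(nrow(ff), 2L)
  sFit <- ff$sigma_nm[1] / 87
  mu <- matrix(ff$background[1], 11, 11)
  for (k in 1:2)
    mu <- mu + ff$amplitude[k] *
      (g(rowsPx, ff$y_nm[k] / 87, sFit) %o% g(colsPx, ff$x_nm[k] / 87, sFit))
  pkgRss <- sum((win - mu)^2)
  expect_lte(pkgRss, bestRss * 1.001)
})

test_that("pixel-to-nm conversion is a pure scale", {
  # the same noiseless emitter imaged at pixel size p and 2p gives the
  # same nm position
  ev <- data.frame(frame = 2L, x_nm = 905.5, y_nm = 843.1)
  mvFine <- renderMovie(ev, 130, 2000, 5, pixelSizeNm = 87,
                        shape = c(21, 21), nFrames = 2, noise = FALSE)
  mvCoarse <- renderMovie(ev, 130, 2000, 20, pixelSizeNm = 174,
                          shape = c(11, 11), nFrames = 2, noise = FALSE)
  fF <- fitSpots(mvFine, data.frame(frame = 2L, row = 11L, col = 11L, value = 1))
  fC <- fitSpots(mvCoarse, data.frame(frame = 2L, row = 6L, col = 6L, value = 1),
                 detectionConfig(fitHalfWidthPx = 4L))
  expect_identical(nrow(fF), 1L)
  expect_identical(nrow(fC), 1L)
  expect_lt(abs(fF$x_nm - fC$x_nm), 0.5)
  expect_lt(abs(fF$y_nm - fC$y_nm), 0.5)
})

test_that("cross-frame merging collapses persisting detections", {
  ev <- data.frame(frame = c(2L, 3L, 10L), x_nm = c(870, 880, 872),
                   y_nm = c(870, 868, 871), amplitude = c(5, 4, 6))
  m <- mergeEvents(ev, mergeGapFrames = 1L, mergeRadiusNm = 100)
  expect_identical(attr(m, "n_raw"), 3L)
  expect_identical(attr(m, "n_merged"), 2L)
  expect_identical(m$frame, c(2L, 10L))
  # a tighter radius prevents any merge
  m2 <- mergeEvents(ev, mergeGapFrames = 1L, mergeRadiusNm = 5)
  expect_identical(nrow(m2), 3L)
})

test_that("ROI assignment matches a ray-casting point-in-polygon oracle", {
  set.seed(5)
  # two disjoint convex-ish polygons
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  tri <- cbind(c(2000, 3000, 2500), c(0, 0, 900))
  rois <- RoiSet(c("a", "b"), list(sq, tri))
  ev <- data.frame(x_nm = runif(300, -500, 3500), y_nm = runif(300, -500, 1500))
  res <- assignToSynapses(ev, rois)
  oracle <- vapply(seq_len(nrow(ev)), function(i) {
    p <- c(ev$x_nm[i], ev$y_nm[i])
    if (pointInPolygonRay(p, sq)) "a"
    else if (pointInPolygonRay(p, tri)) "b"
    else NA_character_
  }, character(1))
  got <- rep(NA_character_, nrow(ev))
  if (nrow(res$assigned)) {
    key <- paste(res$assigned$x_nm, res$assigned$y_nm)
    got[match(key, paste(ev$x_nm, ev$y_nm))] <- res$assigned$synapse_id
  }
  expect_identical(got, oracle)
  expect_identical(nrow(res$assigned) + nrow(res$unassigned), nrow(ev))
})
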