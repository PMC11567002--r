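# Fusion-event detection and sub-pixel localization.
#
# Candidates are local maxima of a band-pass-filtered difference image
# (frame minus rolling baseline). Each candidate window is then fit with
# a mixture of integrated-Gaussian kernels plus a flat background by
# nonlinear least squares; the number of kernels is chosen by a nested
# F-test. Localization precision is the standard error of the fitted
# center, propagated from the parameter covariance of the fit.

#' Detection configuration
#'
#' @param bandpassSigmaPx numeric(2), SDs (px) of the difference-of-
#'   Gaussians band-pass filter; the small scale should match the PSF.
#' @param thresholdSD candidate threshold, in multiples of the robust SD
#'   (MAD) of the unfiltered difference image.
#' @param fitHalfWidthPx half-width of the square fit window (px); the
#'   window spans `2*fitHalfWidthPx + 1` pixels.
#' @param maxKernels maximum Gaussian kernels fit per window.
#' @param modelSelectionAlpha significance level of the nested F-test
#'   that admits an additional kernel.
#' @param psfSigmaNm initial PSF SD (nm); the per-window SD is refined by
#'   the fit.
#' @param precisionCutoffNm fits whose center SE exceeds this are
#'   discarded (and counted).
#' @param rollingBaselineFrames frames averaged into the rolling baseline
#'   subtracted from each frame before filtering.
#' @param mergeGapFrames,mergeRadiusNm parameters of [mergeEvents()]: the
#'   maximum frame gap and distance for merging detections of one release
#'   event persisting across frames.
#'
#' @return A list of class `DetectionConfig`.
#' @examples
#' detectionConfig(thresholdSD = 4)
#' @export
detectionConfig <- function(bandpassSigmaPx = c(1, 3), thresholdSD = 3,
                            fitHalfWidthPx = 5L, maxKernels = 3L,
                            modelSelectionAlpha = 0.05, psfSigmaNm = 130,
                            precisionCutoffNm = 150,
                            rollingBaselineFrames = 3L,
                            mergeGapFrames = 1L, mergeRadiusNm = 100) {
  stopifnot(length(bandpassSigmaPx) == 2L, all(bandpassSigmaPx > 0),
            bandpassSigmaPx[1] < bandpassSigmaPx[2],
            thresholdSD > 0, fitHalfWidthPx >= 1L,
            2L * fitHalfWidthPx + 1L >= 3L,
            maxKernels >= 1L, modelSelectionAlpha > 0,
            modelSelectionAlpha < 1, psfSigmaNm > 0, precisionCutoffNm > 0,
            rollingBaselineFrames >= 1L)
  structure(list(
    bandpassSigmaPx = as.numeric(bandpassSigmaPx),
    thresholdSD = thresholdSD,
    fitHalfWidthPx = as.integer(fitHalfWidthPx),
    maxKernels = as.integer(maxKernels),
    modelSelectionAlpha = modelSelectionAlpha,
    psfSigmaNm = psfSigmaNm,
    precisionCutoffNm = precisionCutoffNm,
    rollingBaselineFrames = as.integer(rollingBaselineFrames),
    mergeGapFrames = as.integer(mergeGapFrames),
    mergeRadiusNm = mergeRadiusNm
  ), class = "DetectionConfig")
}

# Difference-of-Gaussians band-pass. Difference images are ~zero-mean,
# so zero padding keeps small fields of view compatible with the filter
# brush without edge artifacts.
.bandpass <- function(img, sigmas) {
  brush <- 2L * as.integer(ceiling(3 * max(sigmas))) + 1L
  pad <- max(0L, as.integer(ceiling((brush + 1L - min(dim(img))) / 2)))
  if (pad > 0L) {
    big <- matrix(0, nrow(img) + 2L * pad, ncol(img) + 2L * pad)
    big[pad + seq_len(nrow(img)), pad + seq_len(ncol(img))] <- img
    img <- big
  }
  bp <- EBImage::gblur(img, sigma = sigmas[1]) -
    EBImage::gblur(img, sigma = sigmas[2])
  if (pad > 0L)
    bp <- bp[pad + seq_len(nrow(bp) - 2L * pad),
             pad + seq_len(ncol(bp) - 2L * pad), drop = FALSE]
  bp
}

# Local maxima of a matrix: strictly greater than all 8 neighbours.
.localMaxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- ok & (m > p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  which(ok, arr.ind = TRUE)
}

#' Detect candidate fusion events
#'
#' Computes, per frame, a difference image (frame minus the mean of the
#' preceding `rollingBaselineFrames` frames), band-pass filters it with a
#' difference of Gaussians, and returns local maxima whose filtered value
#' exceeds `thresholdSD` times the robust SD (MAD) of the unfiltered
#' difference image. A constant movie yields no candidates.
#'
#' @param movie a [Movie-class].
#' @param cfg a [detectionConfig()].
#'
#' @return data.frame with columns `frame`, `row`, `col` (1-based integer
#'   pixels) and `value` (band-pass response).
#' @export
detectCandidates <- function(movie, cfg = detectionConfig()) {
  stopifnot(is(movie, "Movie"), inherits(cfg, "DetectionConfig"))
  arr <- frames(movie)
  d <- dim(arr)
  out <- vector("list", d[3])
  k <- cfg$rollingBaselineFrames
  for (t in seq_len(d[3])) {
    if (t == 1L) {
      diffImg <- arr[, , 1L] * 0
    } else {
      idx <- max(1L, t - k):(t - 1L)
      base <- if (length(idx) == 1L) arr[, , idx]
              else rowMeans(arr[, , idx, drop = FALSE], dims = 2L)
      diffImg <- arr[, , t] - base
    }
    robustSD <- stats::mad(diffImg)
    bp <- .bandpass(diffImg, cfg$bandpassSigmaPx)
    lm <- .localMaxima(bp)
    if (nrow(lm) == 0L) next
    v <- bp[lm]
    keep <- v > cfg$thresholdSD * robustSD & v > 0
    if (!any(keep)) next
    lm <- lm[keep, , drop = FALSE]
    out[[t]] <- data.frame(frame = t, row = as.integer(lm[, 1]),
                           col = as.integer(lm[, 2]), value = bp[lm])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), row = integer(), col = integer(),
                      value = numeric())
  rownames(res) <- NULL
  res
}

# Model prediction for a window: flat background + k integrated
# Gaussians with shared sigma. Coordinates in px units relative to the
# movie origin (center of pixel (1,1)).
.windowModel <- function(par, k, rowsPx, colsPx) {
  b <- par[1L]; s <- par[2L]
  mu <- matrix(b, length(rowsPx), length(colsPx))
  for (i in seq_len(k)) {
    x <- par[2L + (i - 1L) * 3L + 1L]
    y <- par[2L + (i - 1L) * 3L + 2L]
    A <- par[2L + (i - 1L) * 3L + 3L]
    gx <- stats::pnorm((colsPx + 0.5 - x) / s) -
      stats::pnorm((colsPx - 0.5 - x) / s)
    gy <- stats::pnorm((rowsPx + 0.5 - y) / s) -
      stats::pnorm((rowsPx - 0.5 - y) / s)
    mu <- mu + A * (gy %o% gx)
  }
  mu
}

# Least-squares fit of k kernels to one window. Returns NULL on failure.
.fitWindowK <- function(win, k, rowsPx, colsPx, s0, init) {
  lower <- c(-Inf, max(0.35, s0 / 4),
             rep(c(min(colsPx) - 1, min(rowsPx) - 1, 1e-6), k))
  upper <- c(Inf, s0 * 4,
             rep(c(max(colsPx) + 1, max(rowsPx) + 1, Inf), k))
  fit <- try(minpack.lm::nls.lm(
    par = init,
    lower = lower, upper = upper,
    fn = function(p) as.vector(win - .windowModel(p, k, rowsPx, colsPx)),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  if (!(fit$info %in% 1:4)) return(NULL)
  se <- .sandwichSE(unname(fit$par), k, rowsPx, colsPx)
  list(par = unname(fit$par), se = se,
       rss = sum(fit$fvec^2), n = length(fit$fvec), p = length(fit$par))
}

# Standard errors of the unweighted least-squares estimate under Poisson
# pixel noise: cov = (J'J)^-1 J' diag(mu) J (J'J)^-1, with the Jacobian
# of the window model evaluated numerically at the fitted parameters.
.sandwichSE <- function(par, k, rowsPx, colsPx) {
  mu <- as.vector(.windowModel(par, k, rowsPx, colsPx))
  p <- length(par)
  J <- matrix(0, length(mu), p)
  h <- pmax(1e-6, abs(par) * 1e-6)
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    J[, j] <- as.vector(.windowModel(up, k, rowsPx, colsPx) -
                        .windowModel(dn, k, rowsPx, colsPx)) / (2 * h[j])
  }
  jtj <- crossprod(J)
  inv <- try(solve(jtj), silent = TRUE)
  if (inherits(inv, "try-error")) return(rep(NA_real_, p))
  cov <- inv %*% crossprod(J * pmax(mu, 0), J) %*% inv
  sqrt(pmax(diag(cov), 0))
}

#' Fit candidate windows with integrated-Gaussian mixtures
#'
#' For every candidate, extracts a square window and fits k = 1, 2, ...
#' integrated-Gaussian kernels plus a flat background by nonlinear least
#' squares; k is incremented while a nested F-test improves the fit at
#' `modelSelectionAlpha`, up to `maxKernels`. Kernel centers are reported
#' in nm with their standard errors (localization precision) propagated
#' from the fit covariance. Fits that fail to converge, have non-positive
#' amplitude, land outside the window, or exceed the precision cutoff are
#' discarded and counted by reason; detections from overlapping windows
#' closer than one pixel within a frame are deduplicated (brightest
#' kept).
#'
#' @param movie a [Movie-class].
#' @param candidates data.frame from [detectCandidates()] on the same
#'   movie.
#' @param cfg a [detectionConfig()].
#'
#' @return data.frame with one row per localized event: `frame`, `x_nm`,
#'   `y_nm`, `amplitude` (photons), `background` (photons/px),
#'   `sigma_nm`, `precision_nm`, `n_kernels`. The attribute `"discards"`
#'   holds the per-reason discard counts.
#' @export
fitSpots <- function(movie, candidates, cfg = detectionConfig()) {
  stopifnot(is(movie, "Movie"), is.data.frame(candidates))
  arr <- frames(movie)
  d <- dim(arr)
  px <- pixelSize(movie)
  w <- cfg$fitHalfWidthPx
  s0 <- cfg$psfSigmaNm / px
  discards <- c(no_convergence = 0L, bad_amplitude = 0L,
                outside_window = 0L, low_precision = 0L, duplicate = 0L)
  rows <- list()

  for (ci in seq_len(nrow(candidates))) {
    fr <- candidates$frame[ci]
    r0 <- candidates$row[ci]; c0 <- candidates$col[ci]
    rIdx <- max(1L, r0 - w):min(d[1], r0 + w)
    cIdx <- max(1L, c0 - w):min(d[2], c0 + w)
    win <- arr[rIdx, cIdx, fr]
    rowsPx <- rIdx - 1; colsPx <- cIdx - 1
    if (stats::sd(win) == 0) {
      discards["no_convergence"] <- discards["no_convergence"] + 1L
      next
    }
    b0 <- min(win)
    A0 <- max(sum(win - b0), 1)
    fit1 <- .fitWindowK(win, 1L, rowsPx, colsPx, s0,
                        c(b0, s0, c0 - 1, r0 - 1, A0))
    if (is.null(fit1)) {
      discards["no_convergence"] <- discards["no_convergence"] + 1L
      next
    }
    best <- fit1; k <- 1L
    while (k < cfg$maxKernels) {
      # seed the extra kernel at the largest positive residual
      resid <- win - .windowModel(best$par, k, rowsPx, colsPx)
      mx <- which(resid == max(resid), arr.ind = TRUE)[1, ]
      initK <- c(best$par, colsPx[mx[2]], rowsPx[mx[1]],
                 max(max(resid), 1))
      fitK <- .fitWindowK(win, k + 1L, rowsPx, colsPx, s0, initK)
      if (is.null(fitK) || fitK$rss >= best$rss) break
      dfExtra <- 3
      df2 <- fitK$n - fitK$p
      if (df2 <= 0) break
      Fstat <- ((best$rss - fitK$rss) / dfExtra) / (fitK$rss / df2)
      pval <- stats::pf(Fstat, dfExtra, df2, lower.tail = FALSE)
      if (is.na(pval) || pval >= cfg$modelSelectionAlpha) break
      best <- fitK; k <- k + 1L
    }
    # prune degenerate kernels (vanishing amplitude or center pinned
    # outside the window) and refit with the survivors
    repeat {
      if (k <= 1L) break
      keepK <- vapply(seq_len(k), function(i) {
        off <- 2L + (i - 1L) * 3L
        A <- best$par[off + 3L]
        x <- best$par[off + 1L]; y <- best$par[off + 2L]
        A > 1e-3 && x >= min(colsPx) - 0.75 && x <= max(colsPx) + 0.75 &&
          y >= min(rowsPx) - 0.75 && y <= max(rowsPx) + 0.75
      }, logical(1))
      if (all(keepK) || !any(keepK)) break
      kNew <- sum(keepK)
      initNew <- best$par[1:2]
      for (i in which(keepK))
        initNew <- c(initNew, best$par[2L + (i - 1L) * 3L + 1:3])
      refit <- .fitWindowK(win, kNew, rowsPx, colsPx, s0, initNew)
      if (is.null(refit)) break
      best <- refit; k <- kNew
    }
    bg <- best$par[1L]; sigPx <- best$par[2L]
    for (i in seq_len(k)) {
      off <- 2L + (i - 1L) * 3L
      x <- best$par[off + 1L]; y <- best$par[off + 2L]
      A <- best$par[off + 3L]
      seX <- best$se[off + 1L]; seY <- best$se[off + 2L]
      if (!is.finite(A) || A <= 1e-3) {
        discards["bad_amplitude"] <- discards["bad_amplitude"] + 1L
        next
      }
      if (x < min(colsPx) - 0.5 || x > max(colsPx) + 0.5 ||
          y < min(rowsPx) - 0.5 || y > max(rowsPx) + 0.5) {
        discards["outside_window"] <- discards["outside_window"] + 1L
        next
      }
      prec <- if (all(is.finite(c(seX, seY))))
        sqrt((seX^2 + seY^2) / 2) * px else NA_real_
      if (!is.finite(prec)) {
        discards["no_convergence"] <- discards["no_convergence"] + 1L
        next
      }
      if (prec > cfg$precisionCutoffNm) {
        discards["low_precision"] <- discards["low_precision"] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fr, x_nm = x * px, y_nm = y * px, amplitude = A,
        background = bg, sigma_nm = sigPx * px, precision_nm = prec,
        n_kernels = k)
    }
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev))
    ev <- data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                     amplitude = numeric(), background = numeric(),
                     sigma_nm = numeric(), precision_nm = numeric(),
                     n_kernels = integer())
  # deduplicate same-frame detections closer than one pixel
  if (nrow(ev) > 1L) {
    keep <- rep(TRUE, nrow(ev))
    ord <- order(ev$frame, -ev$amplitude)
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      for (b in seq_along(ord)) {
        if (b <= a) next
        j <- ord[b]
        if (ev$frame[j] != ev$frame[i] || !keep[j]) next
        dd <- sqrt((ev$x_nm[i] - ev$x_nm[j])^2 + (ev$y_nm[i] - ev$y_nm[j])^2)
        if (dd < px) {
          keep[j] <- FALSE
          discards["duplicate"] <- discards["duplicate"] + 1L
        }
      }
    }
    ev <- ev[keep, , drop = FALSE]
  }
  ev <- ev[order(ev$frame, ev$x_nm, ev$y_nm), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "discards") <- discards
  ev
}

#' Merge detections persisting across consecutive frames
#'
#' A single release event can remain visible for more than one frame.
#' Detections within `mergeRadiusNm` of an earlier detection and within
#' `mergeGapFrames` frames of it are merged into that event (the earliest
#' detection is kept). Both merged and raw counts are reported.
#'
#' @param events event data.frame from [fitSpots()].
#' @param mergeGapFrames maximum frame gap (default 1).
#' @param mergeRadiusNm maximum distance in nm (default 100).
#'
#' @return The merged event data.frame; attributes `"n_raw"` and
#'   `"n_merged"` carry the input and merged row counts.
#' @export
mergeEvents <- function(events, mergeGapFrames = 1L, mergeRadiusNm = 100) {
  stopifnot(is.data.frame(events))
  nRaw <- nrow(events)
  if (nRaw <= 1L) {
    attr(events, "n_raw") <- nRaw
    attr(events, "n_merged") <- nRaw
    return(events)
  }
  ev <- events[order(events$frame), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  lastFrame <- ev$frame
  for (i in 2:nrow(ev)) {
    prev <- which(keep[seq_len(i - 1L)])
    if (!length(prev)) next
    gap <- ev$frame[i] - lastFrame[prev]
    cand <- prev[gap >= 1L & gap <= mergeGapFrames]
    if (!length(cand)) next
    dd <- sqrt((ev$x_nm[cand] - ev$x_nm[i])^2 +
               (ev$y_nm[cand] - ev$y_nm[i])^2)
    hit <- cand[which(dd <= mergeRadiusNm)]
    if (length(hit)) {
      keep[i] <- FALSE
      # extend the chain so a long-lived event keeps absorbing frames
      lastFrame[hit[which.min(dd[dd <= mergeRadiusNm])]] <- ev$frame[i]
    }
  }
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discards") <- attr(events, "discards")
  attr(out, "n_raw") <- nRaw
  attr(out, "n_merged") <- nrow(out)
  out
}

#' Assign localized events to synapse ROIs
#'
#' Each event is assigned to the first ROI polygon (in the order of the
#' [RoiSet-class]) that contains it; events contained by no ROI are
#' returned separately.
#'
#' @param events event data.frame with columns `x_nm`, `y_nm`.
#' @param rois a [RoiSet-class].
#'
#' @return list with `assigned` (events plus a `synapse_id` column) and
#'   `unassigned` (the remaining events).
#' @export
assignToSynapses <- function(events, rois) {
  stopifnot(is.data.frame(events), is(rois, "RoiSet"))
  validObject(rois)
  pts <- cbind(events$x_nm, events$y_nm)
  id <- rep(NA_character_, nrow(events))
  for (i in seq_along(roiIds(rois))) {
    poly <- roiPolygons(rois)[[i]]
    if (nrow(events) == 0L) break
    open <- is.na(id)
    if (!any(open)) break
    inside <- mgcv::in.out(rbind(poly, poly[1L, ]), pts[open, , drop = FALSE])
    id[open][inside] <- roiIds(rois)[i]
  }
  assigned <- events[!is.na(id), , drop = FALSE]
  if (nrow(assigned)) assigned$synapse_id <- id[!is.na(id)]
  else assigned$synapse_id <- character(0)
  unassigned <- events[is.na(id), , drop = FALSE]
  rownames(assigned) <- NULL; rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned)
}
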