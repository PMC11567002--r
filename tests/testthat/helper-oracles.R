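# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force linkage, ray casting, numeric
# Fisher information, and direct enumeration.

# Naive O(n^3) complete-linkage agglomeration: repeatedly merge the pair
# of clusters with the smallest maximum inter-point distance while that
# distance is <= h (ties: lexicographically smallest cluster-index pair).
naiveCompleteLinkage <- function(pts, h) {
  n <- nrow(pts)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL; bestD <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- max(sqrt(outer(pts[clusters[[i]], 1], pts[clusters[[j]], 1], "-")^2 +
                    outer(pts[clusters[[i]], 2], pts[clusters[[j]], 2], "-")^2))
      if (d < bestD) { bestD <- d; best <- c(i, j) }
    }
    if (bestD > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assignment <- integer(n)
  for (i in seq_along(clusters)) assignment[clusters[[i]]] <- i
  assignment
}

# Canonical form of a partition label vector: relabel by first appearance
# so two partitions are equal iff their canonical forms are identical.
canonicalPartition <- function(a) {
  match(a, unique(a))
}

# Ray-casting point-in-polygon (crossing number), boundary not special-
# cased (test points are kept off edges).
pointInPolygonRay <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Cramer-Rao lower bound (nm) for the x-center of an integrated-Gaussian
# spot under Poisson noise, computed numerically from the Fisher
# information summed over a window of pixels.
crlbCenterNm <- function(photons, background, psfSigmaNm, pixelSizeNm,
                         halfWidthPx) {
  s <- psfSigmaNm / pixelSizeNm
  px <- -halfWidthPx:halfWidthPx
  g <- function(u, c0) pnorm((u + 0.5 - c0) / s) - pnorm((u - 0.5 - c0) / s)
  dg <- function(u, c0) (dnorm((u - 0.5 - c0) / s) - dnorm((u + 0.5 - c0) / s)) / s
  gx <- g(px, 0); gy <- g(px, 0)
  dgx <- dg(px, 0)
  mu <- background + photons * (gy %o% gx)
  dmu <- photons * (gy %o% dgx)
  Ixx <- sum(dmu^2 / mu)
  pixelSizeNm / sqrt(Ixx)
}

# Noiseless single-spot movie with the event at a known sub-pixel
# position (nm); frame 2 carries the spot so the rolling-baseline
# difference image sees it.
singleSpotMovie <- function(xNm, yNm, photons, background, psfSigmaNm = 130,
                            pixelSizeNm = 87, shape = c(21L, 21L),
                            noise = FALSE, seed = NULL) {
  ev <- data.frame(frame = 2L, x_nm = xNm, y_nm = yNm)
  renderMovie(ev, psfSigmaNm = psfSigmaNm, photonsPerEvent = photons,
              background = background, pixelSizeNm = pixelSizeNm,
              shape = shape, nFrames = 2L, noise = noise, seed = seed)
}

# Rotate points (n x 2) about the origin by angle theta.
rotatePoints <- function(p, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  p %*% t(R)
}
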