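# Active-zone geometry and event distance statistics.

test_that("hull area and center match closed forms", {
  g <- azHull(rbind(c(0, 0), c(100, 0), c(0, 100)))
  expect_equal(azArea(g), 5000)
  expect_equal(azCenter(g), c(100 / 3, 100 / 3))
  expect_false(isDegenerate(g))

  # two events: degenerate, zero area, center still the mean
  g2 <- azHull(rbind(c(0, 0), c(100, 0)))
  expect_true(isDegenerate(g2))
  expect_identical(azArea(g2), 0)
  expect_equal(azCenter(g2), c(50, 0))

  # collinear events: degenerate
  g3 <- azHull(rbind(c(0, 0), c(50, 50), c(100, 100)))
  expect_true(isDegenerate(g3))
  expect_identical(azArea(g3), 0)
})

test_that("hull vertices are counter-clockwise and contain all events", {
  set.seed(3)
  pts <- matrix(rnorm(2 * 50, sd = 150), 50, 2)
  g <- azHull(pts)
  h <- hullVertices(g)
  # CCW: positive shoelace sum
  x <- h[, 1]; y <- h[, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)
  # boundary-inclusive containment of every event
  for (i in seq_len(nrow(pts))) {
    inside <- all(vapply(seq_len(nrow(h)), function(j) {
      a <- h[j, ]; b <- h[if (j == nrow(h)) 1L else j + 1L, ]
      (b[1] - a[1]) * (pts[i, 2] - a[2]) -
        (b[2] - a[2]) * (pts[i, 1] - a[1]) >= -1e-9
    }, logical(1)))
    expect_true(inside)
  }
})

test_that("hull area agrees with a Monte-Carlo membership oracle", {
  set.seed(11)
  for (rep in 1:5) {
    pts <- matrix(runif(2 * 50, 0, 600), 50, 2)
    g <- azHull(pts)
    h <- hullVertices(g)
    n <- 2e5
    q <- cbind(runif(n, 0, 600), runif(n, 0, 600))
    inHull <- rep(TRUE, n)
    nh <- nrow(h)
    for (j in seq_len(nh)) {
      a <- h[j, ]; b <- h[if (j == nh) 1L else j + 1L, ]
      inHull <- inHull &
        ((b[1] - a[1]) * (q[, 2] - a[2]) -
           (b[2] - a[2]) * (q[, 1] - a[1]) >= 0)
    }
    mcArea <- mean(inHull) * 600^2
    expect_lt(abs(azArea(g) - mcArea) / azArea(g),
              0.01 + 3 * sqrt(mcArea * (600^2 - mcArea) / n) / mcArea)
  }
})

test_that("geometry is invariant under rigid motions and idempotent", {
  set.seed(17)
  pts <- matrix(rnorm(2 * 40, sd = 120), 40, 2)
  g <- azHull(pts)
  rot <- rotatePoints(pts, 0.83)
  shift <- cbind(rot[, 1] + 1234.5, rot[, 2] - 987.6)
  g2 <- azHull(shift)
  expect_equal(azArea(g2), azArea(g), tolerance = 1e-9)

  # idempotence: hull of hull vertices is the same polygon
  g3 <- azHull(hullVertices(g))
  expect_equal(azArea(g3), azArea(g), tolerance = 1e-12)
  expect_identical(nrow(hullVertices(g3)), nrow(hullVertices(g)))

  # adding an interior point: hull and area unchanged, center moves
  ctr <- azCenter(g)
  g4 <- azHull(rbind(pts, ctr + c(1, 1)))
  expect_equal(azArea(g4), azArea(g), tolerance = 1e-12)
  expect_identical(nrow(hullVertices(g4)), nrow(hullVertices(g)))
  expect_false(isTRUE(all.equal(azCenter(g4), ctr)))

  # the center is the mean: deviations sum to zero
  dev <- sweep(pts, 2, azCenter(g))
  expect_equal(colSums(dev), c(0, 0), tolerance = 1e-9)
})

test_that("distances to center match symmetry and the uniform-disk limit", {
  g <- azHull(rbind(c(0, 0)))
  d0 <- distancesToCenter(rbind(c(0, 0)), g)
  expect_identical(d0$distances, 0)

  # 4 events at (+-d, 0), (0, +-d): all distances d
  pts <- rbind(c(150, 0), c(-150, 0), c(0, 150), c(0, -150))
  g4 <- azHull(pts)
  d4 <- distancesToCenter(pts, g4)
  expect_equal(d4$distances, rep(150, 4))

  # uniform events in a disk of radius R: mean distance -> 2R/3
  set.seed(29)
  n <- 1e5; R <- 300
  r <- R * sqrt(runif(n)); th <- 2 * pi * runif(n)
  pts <- cbind(r * cos(th), r * sin(th))
  gd <- azHull(pts)
  dd <- distancesToCenter(pts, gd)
  expect_lt(abs(mean(dd$distances) - 2 * R / 3) / (2 * R / 3), 0.02)
  # the distribution columns are a proper distribution
  expect_equal(sum(dd$distribution$fraction), 1)
  expect_equal(dd$distribution$cumulative[nrow(dd$distribution)], 1)
})

test_that("consecutive-event distances follow frame order", {
  ev <- data.frame(frame = c(1L, 5L), x_nm = c(0, 80), y_nm = c(0, 0))
  cc <- consecutiveEventDistances(ev)
  expect_identical(cc$distances, 80)

  # all events at one site: all distances zero
  ev0 <- data.frame(frame = 1:5, x_nm = rep(3, 5), y_nm = rep(4, 5))
  expect_identical(consecutiveEventDistances(ev0)$distances, rep(0, 4))

  # out-of-order input is sorted by frame before differencing
  ev2 <- data.frame(frame = c(3L, 1L, 2L), x_nm = c(200, 0, 100),
                    y_nm = c(0, 0, 0))
  expect_identical(consecutiveEventDistances(ev2)$distances, c(100, 100))
})

test_that("mean consecutive distance matches the site-pair enumeration", {
  # events i.i.d. over K equiprobable sites: the expected consecutive
  # distance is the mean over all ordered site pairs
  az <- makeAZ(4, 250, rep(1, 4), seed = 31, localizationSigmaNm = 0)
  pos <- sitePositions(az)
  pairMean <- mean(sqrt(outer(pos[, 1], pos[, 1], "-")^2 +
                        outer(pos[, 2], pos[, 2], "-")^2))
  set.seed(32)
  n <- 4e4
  pick <- sample(4, n, replace = TRUE)
  ev <- data.frame(frame = seq_len(n), x_nm = pos[pick, 1],
                   y_nm = pos[pick, 2])
  got <- mean(consecutiveEventDistances(ev)$distances)
  expect_lt(abs(got - pairMean) / pairMean, 0.02)
})

test_that("centerShiftSummary reports shifts and a distribution test", {
  set.seed(41)
  a <- runif(500, 0, 300)
  same <- centerShiftSummary(a, a)
  expect_equal(same$test$statistic[[1]], 0)
  expect_gt(same$test$p.value, 0.99)

  shifted <- centerShiftSummary(a, a + 60)
  expect_equal(shifted$meanDiff, 60)
  expect_equal(shifted$medianDiff, 60)
  expect_lt(shifted$test$p.value, 1e-6)
})
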