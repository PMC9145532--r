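test_that("boundary length matches analytic perimeters", {
  m <- rectMask(w = 200, h = 60, px = 1)
  b <- extractBoundary(m)
  per <- sum(sqrt(rowSums(diff(rbind(b, b[1, ]))^2)))
  expect_lt(abs(per - 2 * (200 + 60)) / (2 * 260), 0.02)

  d <- diskMask(R = 60, px = 1)
  bd <- extractBoundary(d)
  perD <- sum(sqrt(rowSums(diff(rbind(bd, bd[1, ]))^2)))
  expect_lt(abs(perD - 2 * pi * 60) / (2 * pi * 60), 0.02)
  ## counter-clockwise orientation with positive enclosed area
  expect_gt(wormAlign:::.signedArea(bd), 0)
})

test_that("tips are found on straight and U-bent tubes; disks rejected", {
  m <- capsuleMask(len = 400, halfWidth = 30, px = 1)
  e <- splitBoundary(extractBoundary(m))
  ## capsule tips at x ~ pad and x ~ pad + 400 on the midline height
  ## curvature is constant along a hemispherical cap, so the exact
  ## split point can sit anywhere on the cap: tips must lie within a
  ## half-width of the midline height and a body length apart
  tips <- e@endpoints[order(e@endpoints[, 1]), ]
  expect_lt(abs(tips[1, 2] - tips[2, 2]), 2 * 30)
  expect_gt(tips[2, 1] - tips[1, 1], 380)

  wU <- synthWorm(bodyLength = 800, halfWidth = 35, bendAngle = pi,
                  nNeurons = 1L, names = NULL, pixelSize = 1.5, seed = 5)
  eU <- splitBoundary(extractBoundary(wU$mask))
  ## both tips lie near x = 0 side of the U, far from the bend apex at
  ## max x; check they are a body-width-scale x but far apart in y
  apexX <- max(extractBoundary(wU$mask)[, 1])
  expect_true(all(eU@endpoints[, 1] < apexX * 0.55))
  expect_gt(abs(eU@endpoints[1, 2] - eU@endpoints[2, 2]), 300)

  expect_error(splitBoundary(extractBoundary(diskMask(R = 50))),
               "elongated")
})

test_that("tangent gap follows its closed form on parallel edges", {
  m <- capsuleMask(len = 400, halfWidth = 30, px = 1)
  e <- splitBoundary(extractBoundary(m))
  s <- 0.5
  sol <- solveTangentRadius(e, s)
  h <- sol$t
  ## tangency: at the solved radius the minimized gap is ~0
  expect_lt(abs(tangentGap(e, s, sol$sPrime, h)), 0.02)
  ## direct evaluation on parallel edges separated by 2h: the gap is
  ## (2h - t) - t, so h at t = h/2 and 2h at t = 0
  expect_lt(abs(tangentGap(e, s, sol$sPrime, h / 2) - h), 0.25)
  expect_lt(abs(tangentGap(e, s, sol$sPrime, 0) - 2 * h), 0.5)
})

test_that("solved radii match constant, tapered and bent widths", {
  ## constant width
  m <- capsuleMask(len = 400, halfWidth = 30, px = 1)
  e <- splitBoundary(extractBoundary(m))
  for (s in c(0.25, 0.5, 0.75))
    expect_lt(abs(solveTangentRadius(e, s)$t - 30) / 30, 0.02)

  ## linear taper: brute-force largest inscribed circle on a dense grid
  wT <- synthWorm(bodyLength = 500, halfWidth = 40, taper = 0.5,
                  bendAngle = 0, nNeurons = 1L, names = NULL,
                  pixelSize = 1, seed = 1)
  eT <- splitBoundary(extractBoundary(wT$mask))
  sol <- solveTangentRadius(eT, 0.5)
  ## brute-force oracle: along the inward normal at the same tangency
  ## foot, the inscribed radius is the root of (distance to the
  ## boundary polygon) - t over candidate radii t
  b <- extractBoundary(wT$mask, nPoints = 2048L)
  foot <- eT@fMinus(0.5)
  nrm <- wormAlign:::.inwardNormal(eT, 0.5)
  ts <- seq(5, 50, by = 0.02)
  gap <- vapply(ts, function(t) {
    cand <- foot + nrm * t
    min(sqrt((b[, 1] - cand[1])^2 + (b[, 2] - cand[2])^2)) - t
  }, numeric(1))
  bruteR <- ts[which.max(gap <= 0)]   # first sign change
  expect_lt(abs(sol$t - bruteR) / bruteR, 0.01)

  ## constant-width bend: radius equals the half width everywhere
  wB <- synthWorm(bodyLength = 600, halfWidth = 40, bendAngle = 1.8,
                  nNeurons = 1L, names = NULL, pixelSize = 0.8, seed = 1)
  eB <- splitBoundary(extractBoundary(wB$mask))
  for (s in c(0.3, 0.5, 0.7))
    expect_lt(abs(solveTangentRadius(eB, s)$t - 40) / 40, 0.01)
})

test_that("circle chains are equally spaced with tangency on both edges", {
  w <- synthWorm(bodyLength = 800, halfWidth = 35, bendAngle = pi / 2,
                 nNeurons = 1L, names = NULL, pixelSize = 1.5, seed = 2)
  e <- splitBoundary(extractBoundary(w$mask))
  ch <- inscribeCircles(e, nCircles = 200)
  expect_equal(length(ch@radii), 200L)
  ## equal spacing in cumulative midline length
  gaps <- diff(ch@cumLength)
  expect_lt(max(abs(gaps - mean(gaps))), 0.05 * mean(gaps))
  ## midline length close to the analytic spine-between-caps length
  expect_lt(abs(max(ch@cumLength) - (800 - 70)) / (800 - 70), 0.01)
  ## tangency invariant: every interior circle touches both edges
  sGrid <- seq(0, 1, length.out = 512)
  mPts <- e@fMinus(sGrid); pPts <- e@fPlus(sGrid)
  for (k in seq(10, 190, by = 20)) {
    dm <- min(sqrt((mPts[, 1] - ch@centers[k, 1])^2 +
                   (mPts[, 2] - ch@centers[k, 2])^2))
    dp <- min(sqrt((pPts[, 1] - ch@centers[k, 1])^2 +
                   (pPts[, 2] - ch@centers[k, 2])^2))
    expect_lt(abs(dm - ch@radii[k]), 1)
    expect_lt(abs(dp - ch@radii[k]), 1)
  }
  ## resampling contract: 3 circles sit at 0, 1/2, 1 of midline length
  ch3 <- inscribeCircles(e, nCircles = 3L)
  expect_equal(length(ch3@radii), 3L)
  expect_equal(ch3@cumLength[2] / ch3@cumLength[3], 0.5, tolerance = 0.01)
})

test_that("straightening preserves midline isometry and keeps z", {
  w <- synthWorm(bodyLength = 800, halfWidth = 35, bendAngle = pi / 2,
                 nNeurons = 60L, pixelSize = 1.5, seed = 3)
  e <- splitBoundary(extractBoundary(w$mask))
  ch <- inscribeCircles(e, nCircles = 200)
  ## midline isometry: adjacent center distances are preserved exactly
  ## by construction of the map (centers k -> (L_k, 0))
  chord <- sqrt(rowSums(diff(ch@centers)^2))
  expect_equal(chord, diff(ch@cumLength), tolerance = 1e-12)
  ## mapped centers land on the x-axis: each center is averaged over
  ## all the neighboring circles containing it, so agreement is at the
  ## sub-micron level rather than exact
  ctrCloud <- pointCloud(cbind(ch@centers, 0))
  mapped <- straightenPoints(ctrCloud, ch, targetExtent = NULL)
  expect_lt(max(abs(coords(mapped)[, 2])), 1)
  expect_lt(max(abs(coords(mapped)[, 1] - ch@cumLength)), 0.1)
  ## z passes through up to the isotropic scale only
  out <- straightenPoints(w$cloud, ch, targetExtent = c(0, 800))
  sc <- 800 / max(ch@cumLength)
  expect_equal(coords(out)[, 3], coords(w$cloud)[, 3] * sc,
               tolerance = 1e-9)
})

test_that("an already-straight worm maps near-identically pre-rescale", {
  w <- synthWorm(bodyLength = 700, halfWidth = 35, bendAngle = 0,
                 nNeurons = 60L, pixelSize = 0.75, seed = 4)
  e <- splitBoundary(extractBoundary(w$mask))
  ch <- inscribeCircles(e, nCircles = 200)
  out <- straightenPoints(w$cloud, ch, targetExtent = NULL)
  p <- coords(w$cloud)
  q <- coords(out)
  ## equality holds up to the translation that puts the midline on
  ## y = 0: fit that translation and bound the residual
  dx <- q[, 1] - p[, 1]
  dy <- q[, 2] - p[, 2]
  disc <- sqrt((dx - mean(dx))^2 + (dy - mean(dy))^2)
  expect_lt(max(disc), 1)
  expect_equal(q[, 3], p[, 3])   # no rescale requested: z untouched
})

test_that("arc-length positions are recovered on a quarter-circle bend", {
  w <- synthWorm(bodyLength = 1000, halfWidth = 40, bendAngle = pi / 2,
                 nNeurons = 80L, pixelSize = 1.5, seed = 6)
  res <- canonicalizeWorm(w$mask, w$cloud, nCircles = 300)
  err <- bestOrientationError(w$cloud, res$transform@chain, w$truth)
  expect_lt(err, 2)
  ## specifically the x (arc-length) coordinate: within 1% of extent
  out <- straightenPoints(w$cloud, res$transform@chain)
  outF <- straightenPoints(w$cloud, res$transform@chain, flipAP = TRUE)
  ex <- min(mean(abs(coords(out)[, 1] - coords(w$truth)[, 1])),
            mean(abs(coords(outF)[, 1] - coords(w$truth)[, 1])))
  expect_lt(ex / 800, 0.01)
})

test_that("canonicalization recovers fixture ground truth end to end", {
  for (ba in c(0, pi)) {
    w <- synthWorm(bodyLength = 1000, halfWidth = 40, bendAngle = ba,
                   nNeurons = 80L, pixelSize = 1.5, seed = 7)
    res <- canonicalizeWorm(w$mask, w$cloud, nCircles = 300)
    expect_lt(bestOrientationError(w$cloud, res$transform@chain, w$truth),
              2)
    expect_identical(frameTag(res$cloud), "canonical")
  }
  ## empty cloud: transform still returned
  w <- synthWorm(bodyLength = 600, halfWidth = 35, bendAngle = 1,
                 nNeurons = 1L, names = NULL, pixelSize = 1.5, seed = 8)
  empty <- pointCloud(matrix(numeric(0), 0, 3))
  res <- canonicalizeWorm(w$mask, empty, nCircles = 100)
  expect_equal(nNeurons(res$cloud), 0L)
  expect_s4_class(res$transform, "CanonicalTransform")
})

test_that("canonicalization is idempotent and mirror-consistent", {
  w <- synthWorm(bodyLength = 800, halfWidth = 35, bendAngle = 1.2,
                 nNeurons = 50L, pixelSize = 1.5, seed = 9)
  e <- splitBoundary(extractBoundary(w$mask))
  ch <- inscribeCircles(e, nCircles = 200)
  once <- straightenPoints(w$cloud, ch, targetExtent = NULL)
  ## straighten an already-straight configuration: build the straight
  ## capsule hull that matches the straightened worm and re-canonicalize
  L <- max(ch@cumLength)
  h <- median(ch@radii)
  wS <- synthWorm(bodyLength = L + 2 * h, halfWidth = h, bendAngle = 0,
                  nNeurons = 1L, names = NULL, pixelSize = 1.5, seed = 1)
  eS <- splitBoundary(extractBoundary(wS$mask))
  chS <- inscribeCircles(eS, nCircles = 200)
  ## place the straightened points into the capsule frame (midline y at
  ## the capsule midline height, x measured from the first circle)
  pts <- coords(once)
  shifted <- pointCloud(cbind(pts[, 1] + chS@centers[1, 1],
                              pts[, 2] + chS@centers[1, 2],
                              pts[, 3]))
  twice <- straightenPoints(shifted, chS, targetExtent = NULL)
  disc <- sqrt(rowSums((coords(twice) - coords(once))^2))
  expect_lt(mean(disc), 2)

  ## mirror: flipping the mask and points about y negates canonical y
  gm <- w$mask@grid[rev(seq_len(nrow(w$mask@grid))), ]
  mMir <- hullMask(gm, w$mask@pixelSize)
  H <- nrow(w$mask@grid) * w$mask@pixelSize
  pm <- coords(w$cloud)
  cloudMir <- pointCloud(cbind(pm[, 1], H - pm[, 2], pm[, 3]))
  eM <- splitBoundary(extractBoundary(mMir))
  chM <- inscribeCircles(eM, nCircles = 200)
  outM <- straightenPoints(cloudMir, chM, targetExtent = NULL)
  ref <- coords(once)
  got <- coords(outM)
  expect_lt(mean(abs(got[, 1] - ref[, 1])), 1.5)
  expect_lt(mean(abs(got[, 2] + ref[, 2])), 1.5)
  expect_equal(got[, 3], ref[, 3], tolerance = 1e-9)
})

test_that("transforms serialize to JSON and back", {
  w <- synthWorm(bodyLength = 600, halfWidth = 35, bendAngle = 1,
                 nNeurons = 20L, pixelSize = 1.5, seed = 10)
  res <- canonicalizeWorm(w$mask, w$cloud, nCircles = 100)
  f <- withr::local_tempfile(fileext = ".json")
  writeTransform(res$transform, f)
  back <- readTransform(f)
  expect_equal(back@chain@centers, res$transform@chain@centers)
  expect_equal(back@scale, res$transform@scale)
  reapplied <- applyCanonical(back, w$cloud)
  expect_equal(coords(reapplied), coords(res$cloud), tolerance = 1e-9)
})
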