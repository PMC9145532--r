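#' @include io.R
NULL

#' EdgeCurvePair: spline-backed opposite body edges
#'
#' The worm hull boundary split at the head and tail tips into two open
#' curves, each fitted with cubic splines parameterized by normalized arc
#' length s in [0, 1] and running head to tail. The "minus" edge is the
#' one whose parameterization follows the counter-clockwise orientation
#' of the full contour, so that the normal (-y', x')/|r'| points into the
#' body, toward the opposite ("plus") edge.
#'
#' @slot fMinus,fPlus functions: s -> 2-column matrix (x, y) in um.
#' @slot dMinus,dPlus derivative functions: s -> 2-column matrix dr/ds.
#' @slot endpoints 2 x 2 matrix: head and tail points (rows), um.
#' @slot plusS,plusSamples dense precomputed samples of the plus edge
#'   (parameter grid and positions) used to seed inner minimizations.
#' @slot bbox numeric(4): xmin, xmax, ymin, ymax of the full boundary.
#' @export
setClass("EdgeCurvePair",
  representation(fMinus = "function", dMinus = "function",
                 fPlus = "function", dPlus = "function",
                 endpoints = "matrix",
                 plusS = "numeric", plusSamples = "matrix",
                 bbox = "numeric"))

setMethod("show", "EdgeCurvePair", function(object) {
  cat(sprintf("EdgeCurvePair: head (%.1f, %.1f) -> tail (%.1f, %.1f) um\n",
    object@endpoints[1, 1], object@endpoints[1, 2],
    object@endpoints[2, 1], object@endpoints[2, 2]))
  invisible(NULL)
})

.polyArcLength <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(d))
}

## resample a closed polyline (first point NOT repeated) to m points
## equally spaced in arc length
.resampleClosed <- function(xy, m) {
  closed <- rbind(xy, xy[1, ])
  len <- .polyArcLength(closed)
  L <- len[length(len)]
  tt <- seq(0, L, length.out = m + 1L)[-(m + 1L)]
  cbind(stats::approx(len, closed[, 1], xout = tt)$y,
        stats::approx(len, closed[, 2], xout = tt)$y)
}

## circular Gaussian smoothing of a closed polyline, sd in vertex units
.smoothClosed <- function(xy, sdPts) {
  m <- nrow(xy)
  half <- max(1L, ceiling(3 * sdPts))
  k <- stats::dnorm(-half:half, sd = sdPts)
  k <- k / sum(k)
  smoothCol <- function(v) {
    ext <- c(v[(m - half + 1L):m], v, v[1:half])
    stats::filter(ext, k, sides = 2)[(half + 1L):(half + m)]
  }
  cbind(as.numeric(smoothCol(xy[, 1])), as.numeric(smoothCol(xy[, 2])))
}

.signedArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## simple-polygon check on a decimated copy (O(m^2) segment pairs)
.isSimplePolygon <- function(xy, m = 200L) {
  if (nrow(xy) > m) xy <- .resampleClosed(xy, m)
  n <- nrow(xy)
  p <- xy
  q <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    d3 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2],
                rep(p[i, 1], length(js)), rep(p[i, 2], length(js)))
    d4 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2],
                rep(q[i, 1], length(js)), rep(q[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Extract the worm body outline from a hull mask
#'
#' Traces the 0.5-level contour of the binary mask (sub-pixel, by linear
#' interpolation between pixel centers), keeps the longest closed curve,
#' resamples it to uniform arc-length spacing and applies a small circular
#' Gaussian smoothing (about one pixel) so the curve is C1 for the
#' tangent-circle construction.
#'
#' @param mask a [HullMask-class].
#' @param nPoints number of points on the returned contour (default 512).
#' @param smoothPx smoothing bandwidth in pixels (default 1).
#' @return closed, simple, counter-clockwise contour: an nPoints x 2
#'   matrix (x, y) in micrometres; the first point is not repeated.
#' @export
extractBoundary <- function(mask, nPoints = 512L, smoothPx = 1) {
  stopifnot(is(mask, "HullMask"))
  validObject(mask)
  g <- mask@grid
  px <- mask@pixelSize
  ## x along columns, y along rows; pixel centers at (i - 0.5) * px
  xs <- (seq_len(ncol(g)) - 0.5) * px
  ys <- (seq_len(nrow(g)) - 0.5) * px
  cl <- grDevices::contourLines(xs, ys, t(matrix(as.numeric(g), nrow(g))),
                                levels = 0.5)
  if (!length(cl)) stop("no boundary found in mask")
  lens <- vapply(cl, function(cc)
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), numeric(1))
  cc <- cl[[which.max(lens)]]
  xy <- cbind(cc$x, cc$y)
  ## drop a duplicated closing vertex if present
  if (sum((xy[1, ] - xy[nrow(xy), ])^2) < 1e-12) xy <- xy[-nrow(xy), ]
  xy <- .resampleClosed(xy, nPoints)
  ## smoothing sd: one pixel expressed in vertex units
  per <- sum(sqrt(rowSums(diff(rbind(xy, xy[1, ]))^2)))
  sdPts <- smoothPx * px / (per / nPoints)
  if (sdPts > 0.2) xy <- .smoothClosed(xy, sdPts)
  if (.signedArea(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  if (!.isSimplePolygon(xy))
    stop("boundary self-intersects after smoothing")
  colnames(xy) <- c("x", "y")
  xy
}

## turning-angle curvature magnitude at each vertex of a closed polyline
.closedCurvature <- function(xy) {
  m <- nrow(xy)
  prv <- xy[c(m, 1:(m - 1L)), ]
  nxt <- xy[c(2:m, 1L), ]
  v1 <- xy - prv
  v2 <- nxt - xy
  a1 <- atan2(v1[, 2], v1[, 1])
  a2 <- atan2(v2[, 2], v2[, 1])
  da <- a2 - a1
  da <- atan2(sin(da), cos(da))
  ds <- (sqrt(rowSums(v1^2)) + sqrt(rowSums(v2^2))) / 2
  abs(da) / pmax(ds, .Machine$double.eps)
}

.openSpline <- function(xy) {
  len <- .polyArcLength(xy)
  s <- len / len[length(len)]
  ## arc-length parameter can have coincident knots after smoothing
  keep <- c(TRUE, diff(s) > 1e-12)
  s <- s[keep]; xy <- xy[keep, , drop = FALSE]
  fx <- stats::splinefun(s, xy[, 1], method = "natural")
  fy <- stats::splinefun(s, xy[, 2], method = "natural")
  list(
    f = function(ss) cbind(fx(ss), fy(ss)),
    d = function(ss) cbind(fx(ss, deriv = 1), fy(ss, deriv = 1)),
    length = len[length(len)]
  )
}

#' Split a body outline into opposite edge curves at the tips
#'
#' Chooses the head and tail as the pair of boundary points at maximal
#' Euclidean separation, refined to the nearest local curvature maxima
#' (body tips are high-curvature caps), then splits the contour into the
#' two opposite edges and fits each with cubic splines parameterized by
#' normalized arc length.
#'
#' @param contour closed CCW contour from [extractBoundary()] (n x 2, um).
#' @param minElongation reject shapes whose tip separation is below this
#'   multiple of the equal-area disk diameter (default 1.3); a disk or
#'   near-disk has no stable tip pair.
#' @return an [EdgeCurvePair-class]
#' @export
splitBoundary <- function(contour, minElongation = 1.3) {
  m <- nrow(contour)
  if (m < 16L) stop("contour has too few points")
  ## approximate farthest pair on a decimated copy, then refine locally
  dec <- if (m > 256L) round(seq(1L, m, length.out = 256L)) else seq_len(m)
  D <- as.matrix(stats::dist(contour[dec, ]))
  ij <- arrayInd(which.max(D), dim(D))
  i0 <- dec[ij[1]]; j0 <- dec[ij[2]]
  refineFar <- function(i, jFixed, halfWin) {
    win <- ((i - halfWin):(i + halfWin) - 1L) %% m + 1L
    d2 <- rowSums((contour[win, , drop = FALSE] -
                   matrix(contour[jFixed, ], length(win), 2,
                          byrow = TRUE))^2)
    win[which.max(d2)]
  }
  hw <- max(2L, round(m / 64))
  for (it in 1:4) {
    i0 <- refineFar(i0, j0, hw)
    j0 <- refineFar(j0, i0, hw)
  }
  maxDist <- sqrt(sum((contour[i0, ] - contour[j0, ])^2))
  areaDiam <- 2 * sqrt(abs(.signedArea(contour)) / pi)
  if (maxDist < minElongation * areaDiam)
    stop(sprintf(paste0("shape is not elongated enough to identify tips ",
      "(tip separation %.1f um vs equal-area diameter %.1f um)"),
      maxDist, areaDiam))
  ## refine each tip to a local curvature maximum; curvature is taken on
  ## a heavily smoothed copy so residual pixel noise on straight
  ## stretches cannot outscore the genuine tip caps
  curv <- .closedCurvature(.smoothClosed(contour, max(2, m / 100)))
  refineCurv <- function(i, halfWin) {
    win <- ((i - halfWin):(i + halfWin) - 1L) %% m + 1L
    win[which.max(curv[win])]
  }
  cw <- max(2L, round(0.05 * m))
  i0 <- refineCurv(i0, cw)
  j0 <- refineCurv(j0, cw)
  if (i0 == j0) stop("degenerate tip pair")
  ## deterministic head choice: smaller (x, then y); flip downstream if needed
  pi0 <- contour[i0, ]; pj0 <- contour[j0, ]
  if (pj0[1] < pi0[1] || (pj0[1] == pi0[1] && pj0[2] < pi0[2])) {
    tmp <- i0; i0 <- j0; j0 <- tmp
  }
  ## arc following CCW order from head to tail keeps the CCW orientation,
  ## so its inward normal is (-y', x'); the other arc is reversed
  idxA <- if (i0 <= j0) i0:j0 else c(i0:m, 1:j0)
  idxB <- if (j0 <= i0) j0:i0 else c(j0:m, 1:i0)
  arcMinus <- contour[idxA, , drop = FALSE]
  arcPlus <- contour[rev(idxB), , drop = FALSE]
  if (nrow(arcMinus) < 4L || nrow(arcPlus) < 4L)
    stop("tip split produced a degenerate edge")
  spM <- .openSpline(arcMinus)
  spP <- .openSpline(arcPlus)
  sGrid <- seq(0, 1, length.out = 1024L)
  new("EdgeCurvePair",
      fMinus = spM$f, dMinus = spM$d, fPlus = spP$f, dPlus = spP$d,
      endpoints = rbind(head = contour[i0, ], tail = contour[j0, ]),
      plusS = sGrid, plusSamples = spP$f(sGrid),
      bbox = c(range(contour[, 1]), range(contour[, 2])))
}

.inwardNormal <- function(edges, s) {
  d <- edges@dMinus(s)
  n <- cbind(-d[, 2], d[, 1])
  n / sqrt(rowSums(n^2))
}

#' Signed gap between a candidate tangent circle and the opposite edge
#'
#' For a circle of radius t tangent to the minus edge at parameter s
#' (center on the inward normal), returns the distance from its center to
#' the point at parameter sPrime on the plus edge, minus t. A zero value
#' means the circle touches the plus edge at that point.
#'
#' @param edges an [EdgeCurvePair-class].
#' @param s,sPrime edge parameters in [0, 1].
#' @param t candidate radius, micrometres (>= 0).
#' @return signed distance in micrometres.
#' @export
tangentGap <- function(edges, s, sPrime, t) {
  stopifnot(s >= 0, s <= 1, sPrime >= 0, sPrime <= 1, t >= 0)
  center <- edges@fMinus(s) + .inwardNormal(edges, s) * t
  sqrt(sum((center - edges@fPlus(sPrime))^2)) - t
}

## min over sPrime of the gap, via the dense grid + local refinement
.minGap <- function(edges, center, t) {
  d2 <- (edges@plusSamples[, 1] - center[1])^2 +
        (edges@plusSamples[, 2] - center[2])^2
  k <- which.min(d2)
  lo <- edges@plusS[max(1L, k - 1L)]
  hi <- edges@plusS[min(length(edges@plusS), k + 1L)]
  g <- function(sp) {
    p <- edges@fPlus(sp)
    sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2)
  }
  opt <- stats::optimize(g, c(lo, hi), tol = 1e-6)
  best <- min(opt$objective, sqrt(d2[k]))
  spBest <- if (opt$objective <= sqrt(d2[k])) opt$minimum else edges@plusS[k]
  list(gap = best - t, sPrime = spBest)
}

## Gaussian smoothing of an open sequence with reflection padding
.smoothOpen <- function(v, sdPts) {
  m <- length(v)
  half <- min(m - 1L, max(1L, ceiling(3 * sdPts)))
  k <- stats::dnorm(-half:half, sd = sdPts)
  k <- k / sum(k)
  ext <- c(2 * v[1] - v[(half + 1L):2], v, 2 * v[m] - v[(m - 1L):(m - half)])
  as.numeric(stats::filter(ext, k, sides = 2)[(half + 1L):(half + m)])
}

## default radius bracket: generously above any inscribable radius (the
## minor bounding-box dimension can equal the tube width exactly, so a
## 0.5 factor would put the bracket end right on the root)
.defaultTMax <- function(edges) {
  mn <- min(edges@bbox[2] - edges@bbox[1], edges@bbox[4] - edges@bbox[3])
  mx <- max(edges@bbox[2] - edges@bbox[1], edges@bbox[4] - edges@bbox[3])
  max(0.75 * mn, min(mn, 0.5 * mx))
}

#' Solve for the inscribed tangent-circle radius at parameter s
#'
#' Finds the radius t(s) at which the circle tangent to the minus edge at
#' s also touches the plus edge: the root of the minimized gap, found by
#' bracketed root-finding over t with the inner minimization over sPrime
#' done on a dense grid followed by local refinement.
#'
#' @param edges an [EdgeCurvePair-class].
#' @param s interior edge parameter.
#' @param tMax radius bracket upper bound; by default a generous
#'   multiple of the boundary bounding-box minor dimension.
#' @param tol radius tolerance in micrometres (default 1e-3).
#' @return list with elements \code{t} (radius, um) and \code{sPrime}
#'   (touch parameter on the plus edge). Errors when no root lies in the
#'   bracket (e.g. too close to the tips).
#' @export
solveTangentRadius <- function(edges, s, tMax = NULL, tol = 1e-3) {
  stopifnot(s > 0, s < 1)
  if (is.null(tMax)) tMax <- .defaultTMax(edges)
  base <- edges@fMinus(s)
  nrm <- .inwardNormal(edges, s)
  gapAt <- function(t) .minGap(edges, base + nrm * t, t)
  fLo <- gapAt(tol)
  fHi <- gapAt(tMax)
  if (fLo$gap <= 0 || fHi$gap > 0)
    stop(sprintf("no tangent radius in (0, %.3g] at s = %.4f", tMax, s))
  root <- stats::uniroot(function(t) gapAt(t)$gap, c(tol, tMax),
                         f.lower = fLo$gap, f.upper = fHi$gap, tol = tol)
  list(t = root$root, sPrime = gapAt(root$root)$sPrime)
}

#' Inscribe the chain of tangent circles
#'
#' Solves the tangent radius on a dense grid of interior s values, builds
#' the center polyline (center = minus-edge point plus inward normal times
#' radius), and resamples it to \code{nCircles} circles equally spaced in
#' cumulative midline arc length.
#'
#' @param edges an [EdgeCurvePair-class].
#' @param nCircles number of circles (default 1000).
#' @param nSolve number of s values at which the radius is solved before
#'   resampling (default \code{max(nCircles, 256)}).
#' @return a [CircleChain-class]
#' @export
inscribeCircles <- function(edges, nCircles = 1000L,
                            nSolve = max(nCircles, 256L)) {
  stopifnot(nCircles >= 3L)
  sGrid <- seq(0, 1, length.out = nSolve + 2L)[2:(nSolve + 1L)]
  tMax <- .defaultTMax(edges)
  sols <- lapply(sGrid, function(s)
    tryCatch(solveTangentRadius(edges, s, tMax = tMax),
             error = function(e) NULL))
  ok <- !vapply(sols, is.null, logical(1))
  if (sum(ok) < 3L)
    stop("fewer than 3 solvable tangent circles; hull may be degenerate")
  sOk <- sGrid[ok]
  tOk <- vapply(sols[ok], `[[`, numeric(1), "t")
  centers <- edges@fMinus(sOk) + .inwardNormal(edges, sOk) * tOk
  ## inside the rounded tip caps the tangency problem follows a second
  ## branch of small circles shrinking toward the split point; the
  ## midline proper ends at the cap center, so trim the ends while the
  ## radius sits well below the nearby stable body radius
  refs <- NULL
  if (length(tOk) >= 7L) {
    win <- min(length(tOk), max(7L, 2L * (length(tOk) %/% 16L) + 1L))
    med <- stats::runmed(tOk, win)
    nref <- max(3L, round(0.15 * length(tOk)))
    refs <- c(head = med[nref], tail = med[length(med) - nref + 1L])
    i1 <- which(tOk >= 0.92 * refs["head"])[1]
    i2 <- max(which(tOk >= 0.92 * refs["tail"]))
    if (!is.na(i1) && i1 <= i2) {
      sOk <- sOk[i1:i2]; tOk <- tOk[i1:i2]
      centers <- centers[i1:i2, , drop = FALSE]
    }
  }
  ## remaining multi-modal alternation: reject radius outliers against a
  ## running median, then drop centers that backtrack along the path
  if (length(tOk) >= 7L) {
    med <- stats::runmed(tOk, 7L)
    keep <- abs(tOk - med) <= pmax(0.15 * med, 1)
    sOk <- sOk[keep]; tOk <- tOk[keep]
    centers <- centers[keep, , drop = FALSE]
  }
  repeat {
    k <- nrow(centers)
    if (k < 3L) break
    v1 <- centers[2:(k - 1L), , drop = FALSE] -
          centers[1:(k - 2L), , drop = FALSE]
    v2 <- centers[3:k, , drop = FALSE] - centers[2:(k - 1L), , drop = FALSE]
    bad <- which(rowSums(v1 * v2) < 0) + 1L
    if (!length(bad)) break
    drop <- bad[c(TRUE, diff(bad) > 1L)]
    sOk <- sOk[-drop]; tOk <- tOk[-drop]
    centers <- centers[-drop, , drop = FALSE]
  }
  if (length(tOk) < 3L)
    stop("fewer than 3 stable tangent circles; hull may be degenerate")
  ## light smoothing of the center polyline: per-center noise of a few
  ## tenths of a micron would otherwise inflate the cumulative arc
  ## length systematically (random-walk excess of sigma^2 / spacing per
  ## segment); at midline bend radii far above the smoothing span the
  ## geometric shrinkage this causes is negligible
  if (nrow(centers) >= 9L) {
    sdPts <- max(2, length(tOk) / 100)
    centers <- apply(centers, 2, .smoothOpen, sdPts = sdPts)
    tOk <- .smoothOpen(tOk, sdPts = sdPts)
  }
  ## resample to equal spacing in cumulative midline arc length; the
  ## midline is taken to end at the tip-cap centers: a remaining
  ## cap-branch circle of radius t sits (h - t) away from the cap
  ## center (h the stable body radius at that end), so each end is
  ## clipped (or, if the chain stops early, extended) by that deficit
  len <- .polyArcLength(centers)
  L <- len[length(len)]
  clipH <- 0; clipT <- 0
  if (!is.null(refs)) {
    clipH <- refs[["head"]] - tOk[1]
    clipT <- refs[["tail"]] - tOk[length(tOk)]
  }
  target <- seq(clipH, L - clipT, length.out = nCircles)
  interp <- function(v) {
    out <- stats::approx(len, v, xout = pmin(pmax(target, 0), L),
                         ties = "ordered")$y
    ## linear extrapolation for ends clipped outward (negative deficit)
    lo <- target < 0
    if (any(lo))
      out[lo] <- v[1] + (v[2] - v[1]) / (len[2] - len[1]) * target[lo]
    hiI <- target > L
    if (any(hiI)) {
      k <- length(v)
      out[hiI] <- v[k] + (v[k] - v[k - 1]) / (len[k] - len[k - 1]) *
        (target[hiI] - L)
    }
    out
  }
  cx <- interp(centers[, 1])
  cy <- interp(centers[, 2])
  rr <- pmax(interp(tOk), 1e-6)
  ss <- interp(sOk)
  ## enforce strictly increasing s (flat stretches can tie after approx)
  if (any(diff(ss) <= 0)) ss <- cummax(ss + seq_along(ss) * 1e-12)
  ctr <- cbind(cx, cy)
  cum <- .polyArcLength(ctr)
  new("CircleChain", centers = unname(ctr), radii = rr, s = ss,
      cumLength = cum)
}

## unit tangents along the center polyline by central differences over a
## widened window (about 1% of the chain): single-step differences pick
## up sub-pixel center noise as rotation noise, which a neuron at the
## tube wall sees amplified by its lever arm
.chainTangents <- function(ctr) {
  k <- nrow(ctr)
  w <- max(1L, round(k / 100))
  lo <- pmax(seq_len(k) - w, 1L)
  hi <- pmin(seq_len(k) + w, k)
  tx <- ctr[hi, 1] - ctr[lo, 1]
  ty <- ctr[hi, 2] - ctr[lo, 2]
  tn <- sqrt(tx^2 + ty^2)
  list(ct = tx / tn, st = ty / tn)
}

#' Straighten neuron positions with a circle chain
#'
#' Each circle k defines a rigid xy map sending its center to (L_k, 0) --
#' L_k its cumulative midline arc length -- and rotating the local midline
#' tangent onto +x. Every neuron is mapped by all circles whose xy
#' projection contains it and the images are averaged; a neuron inside no
#' circle uses the nearest-center circle. z passes through unchanged.
#' Finally all coordinates are isotropically rescaled so that the midline
#' spans the target x extent (head at the low end unless \code{flipAP}).
#'
#' @param points a [NeuronPointCloud-class] in the same raw frame as the
#'   chain.
#' @param chain a [CircleChain-class].
#' @param targetExtent canonical x-range in um (default c(0, 800)), or
#'   NULL to skip the final isotropic rescale.
#' @param flipAP logical: flip the anterior-posterior axis (a rigid 180
#'   degree rotation about z in the canonical frame).
#' @return a canonical-frame [NeuronPointCloud-class].
#' @export
straightenPoints <- function(points, chain, targetExtent = c(0, 800),
                             flipAP = FALSE) {
  stopifnot(is(points, "NeuronPointCloud"), is(chain, "CircleChain"))
  n <- nNeurons(points)
  L <- chain@cumLength[length(chain@cumLength)]
  scale <- if (is.null(targetExtent)) 1
           else (targetExtent[2] - targetExtent[1]) / L
  if (n == 0L) {
    out <- points
    out@frameTag <- "canonical"
    return(out)
  }
  ctr <- chain@centers
  k <- nrow(ctr)
  tg <- .chainTangents(ctr)
  ct <- tg$ct
  st <- tg$st
  p <- coords(points)
  qx <- outer(p[, 1], ctr[, 1], "-")   # n x k
  qy <- outer(p[, 2], ctr[, 2], "-")
  Ct <- matrix(ct, n, k, byrow = TRUE)
  St <- matrix(st, n, k, byrow = TRUE)
  Lk <- matrix(chain@cumLength, n, k, byrow = TRUE)
  Xp <- Ct * qx + St * qy + Lk
  Yp <- -St * qx + Ct * qy
  dist2 <- qx^2 + qy^2
  member <- dist2 <= matrix(chain@radii^2, n, k, byrow = TRUE)
  nm <- rowSums(member)
  none <- nm == 0L
  if (any(none)) {
    nearest <- max.col(-dist2[none, , drop = FALSE])
    member[cbind(which(none), nearest)] <- TRUE
    nm[none] <- 1L
  }
  xNew <- rowSums(Xp * member) / nm
  yNew <- rowSums(Yp * member) / nm
  zNew <- p[, 3]
  if (flipAP) {
    xNew <- L - xNew
    yNew <- -yNew
  }
  out <- cbind(x = xNew * scale + if (is.null(targetExtent)) 0
                                  else targetExtent[1],
               y = yNew * scale,
               z = zNew * scale)
  pointCloud(out, ids = if (length(points@ids)) points@ids else NULL,
             colors = if (length(points@colors)) points@colors else NULL,
             frameTag = "canonical")
}

#' Canonicalize a worm end to end
#'
#' Composes boundary extraction, tip splitting, circle inscription and
#' point straightening, returning both the canonical cloud and the
#' reusable transform.
#'
#' @param mask a [HullMask-class].
#' @param points a [NeuronPointCloud-class] co-registered with the mask
#'   (micrometres in the same frame).
#' @param nCircles number of inscribed circles (default 1000).
#' @param targetExtent canonical x-range (default c(0, 800) um).
#' @param flipAP flip the anterior-posterior orientation.
#' @return list with elements \code{cloud} (canonical
#'   [NeuronPointCloud-class]) and \code{transform}
#'   ([CanonicalTransform-class]).
#' @export
canonicalizeWorm <- function(mask, points, nCircles = 1000L,
                             targetExtent = c(0, 800), flipAP = FALSE) {
  contour <- extractBoundary(mask)
  edges <- splitBoundary(contour)
  chain <- inscribeCircles(edges, nCircles = nCircles)
  cloud <- straightenPoints(points, chain, targetExtent = targetExtent,
                            flipAP = flipAP)
  L <- chain@cumLength[length(chain@cumLength)]
  tf <- new("CanonicalTransform", chain = chain,
            scale = (targetExtent[2] - targetExtent[1]) / L,
            targetExtent = as.numeric(targetExtent), flipAP = flipAP)
  list(cloud = cloud, transform = tf)
}

#' Apply a stored canonical transform to new points
#'
#' @param transform a [CanonicalTransform-class].
#' @param points a raw-frame [NeuronPointCloud-class].
#' @return canonical [NeuronPointCloud-class]
#' @export
applyCanonical <- function(transform, points) {
  straightenPoints(points, transform@chain,
                   targetExtent = transform@targetExtent,
                   flipAP = transform@flipAP)
}

#' Serialize / restore a canonical transform as JSON
#'
#' @param transform a [CanonicalTransform-class]
#' @param path JSON file path
#' @return \code{writeTransform}: invisibly, \code{path};
#'   \code{readTransform}: a [CanonicalTransform-class].
#' @export
writeTransform <- function(transform, path) {
  ch <- transform@chain
  jsonlite::write_json(list(
    centers = ch@centers, radii = ch@radii, s = ch@s,
    cumLength = ch@cumLength, scale = transform@scale,
    targetExtent = transform@targetExtent, flipAP = transform@flipAP),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chain <- new("CircleChain", centers = as.matrix(obj$centers),
               radii = as.numeric(obj$radii), s = as.numeric(obj$s),
               cumLength = as.numeric(obj$cumLength))
  new("CanonicalTransform", chain = chain, scale = as.numeric(obj$scale),
      targetExtent = as.numeric(obj$targetExtent),
      flipAP = as.logical(obj$flipAP))
}

#' Basic skeleton-free midline straightening (baseline)
#'
#' A simple baseline straightener: x = arc length along the midline,
#' y = signed perpendicular distance to it. Provided only for benchmark
#' comparison against the inscribed-circle method; it distorts volume at
#' bends.
#'
#' @inheritParams straightenPoints
#' @return canonical [NeuronPointCloud-class]
#' @export
straightenPointsBasic <- function(points, chain, targetExtent = c(0, 800),
                                  flipAP = FALSE) {
  stopifnot(is(points, "NeuronPointCloud"), is(chain, "CircleChain"))
  n <- nNeurons(points)
  L <- chain@cumLength[length(chain@cumLength)]
  scale <- if (is.null(targetExtent)) 1
           else (targetExtent[2] - targetExtent[1]) / L
  if (n == 0L) { out <- points; out@frameTag <- "canonical"; return(out) }
  ctr <- chain@centers
  p <- coords(points)
  d2 <- outer(p[, 1], ctr[, 1], "-")^2 + outer(p[, 2], ctr[, 2], "-")^2
  nearest <- max.col(-d2)
  tg <- .chainTangents(ctr)
  qx <- p[, 1] - ctr[nearest, 1]
  qy <- p[, 2] - ctr[nearest, 2]
  xNew <- chain@cumLength[nearest] +
    tg$ct[nearest] * qx + tg$st[nearest] * qy
  yNew <- -tg$st[nearest] * qx + tg$ct[nearest] * qy
  if (flipAP) { xNew <- L - xNew; yNew <- -yNew }
  out <- cbind(x = xNew * scale + if (is.null(targetExtent)) 0
                                  else targetExtent[1],
               y = yNew * scale, z = p[, 3] * scale)
  pointCloud(out, ids = if (length(points@ids)) points@ids else NULL,
             colors = if (length(points@colors)) points@colors else NULL,
             frameTag = "canonical")
}
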