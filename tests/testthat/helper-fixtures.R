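## shared fixture builders (all deterministic under the given seed)

## random labeled cloud with a minimum pairwise separation, inside a box
separatedCloud <- function(n, minDist = 15, box = c(300, 300, 300),
                           seed = 1) {
  withr::with_seed(seed, {
    P <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(P) < n && tries < 50000L) {
      cand <- runif(3) * box
      if (nrow(P) == 0L ||
          min(sqrt(rowSums(sweep(P, 2, cand)^2))) >= minDist)
        P <- rbind(P, cand)
      tries <- tries + 1L
    }
    stopifnot(nrow(P) == n)
    pointCloud(P, ids = sprintf("n%03d", seq_len(n)),
               frameTag = "canonical")
  })
}

## capsule (straight tube with hemispherical caps) mask built directly
capsuleMask <- function(len = 400, halfWidth = 30, px = 1) {
  synthWorm(bodyLength = len, halfWidth = halfWidth, bendAngle = 0,
            nNeurons = 1L, names = NULL, pixelSize = px, seed = 1)$mask
}

## rectangle mask (sharp corners) for boundary-length checks
rectMask <- function(w = 200, h = 60, px = 1, pad = 6) {
  nr <- round(h / px) + 2 * pad
  nc <- round(w / px) + 2 * pad
  g <- matrix(FALSE, nr, nc)
  g[(pad + 1):(nr - pad), (pad + 1):(nc - pad)] <- TRUE
  hullMask(g, px)
}

diskMask <- function(R = 60, px = 1, pad = 6) {
  n <- round(2 * R / px) + 2 * pad
  ctr <- (n + 1) / 2
  idx <- seq_len(n)
  d2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
  hullMask(d2 <= (R / px)^2, px)
}

## orientation-aware comparison against fixture ground truth: the mask
## alone cannot identify which tip is the head, so take the better of
## the two anterior-posterior orientations
bestOrientationError <- function(cloud, chain, truth,
                                 targetExtent = c(0, 800)) {
  errOf <- function(cl)
    mean(sqrt(rowSums((coords(cl) - coords(truth))^2)))
  e1 <- errOf(straightenPoints(cloud, chain, targetExtent = targetExtent))
  e2 <- errOf(straightenPoints(cloud, chain, targetExtent = targetExtent,
                               flipAP = TRUE))
  min(e1, e2)
}

## scalar double-loop evaluation of the generalized-mean loss (oracle);
## deliberately naive and independent of the vectorized implementation
gmLossOracle <- function(P1, P2, c1 = NULL, c2 = NULL, gamma = -6,
                         epsilon = 1e-3) {
  total <- 0
  for (j in seq_len(nrow(P2))) {
    vals <- c()
    for (i in seq_len(nrow(P1))) {
      same <- is.null(c1) || is.null(c2) || c1[i] == c2[j]
      if (!same) next
      d <- sqrt(sum((P1[i, ] - P2[j, ])^2))
      vals <- c(vals, sqrt(d^2 + epsilon^2))
    }
    total <- total + mean(vals^gamma)^(1 / gamma)
  }
  total
}

## brute-force optimal assignment over all permutations (small n)
bruteOptimalAssignment <- function(D) {
  n <- nrow(D)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(D[cbind(seq_len(n), p)])
    if (cost < bestCost) { bestCost <- cost; best <- p }
  }
  best
}
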