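#' @include pointcloud.R
NULL

.coordsOf <- function(x) {
  if (is(x, "Atlas")) x <- asPointCloud(x)
  if (is(x, "NeuronPointCloud")) return(coords(x))
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  x
}

.colorsOf <- function(x) {
  if (is(x, "Atlas")) x <- asPointCloud(x)
  if (is(x, "NeuronPointCloud")) {
    if (length(neuronColors(x))) return(neuronColors(x))
  }
  NULL
}

## color classes shared by a labeled/unlabeled pair; colorless = 1 class
.colorClasses <- function(c1, n1, c2, n2) {
  if (is.null(c1) || is.null(c2)) {
    return(list(list(i = seq_len(n1), j = seq_len(n2))))
  }
  missing <- setdiff(unique(c2), unique(c1))
  if (length(missing))
    stop("unlabeled color(s) absent from the labeled cloud: ",
         paste(sort(missing), collapse = ", "))
  lapply(intersect(unique(c2), unique(c1)), function(cc)
    list(i = which(c1 == cc), j = which(c2 == cc)))
}

## loss and gradient (w.r.t. the unlabeled positions P2) of the
## generalized-mean loss, numerically stabilized by factoring out the
## per-point minimum distance so that gamma as low as -50 stays finite
.gmCore <- function(P1, P2, c1, c2, gamma, epsilon, wantGrad = FALSE) {
  n1 <- nrow(P1); n2 <- nrow(P2)
  classes <- .colorClasses(c1, n1, c2, n2)
  loss <- 0
  perPoint <- numeric(n2)
  grad <- if (wantGrad) matrix(0, n2, 3) else NULL
  for (cl in classes) {
    A1 <- P1[cl$i, , drop = FALSE]
    A2 <- P2[cl$j, , drop = FALSE]
    m <- nrow(A1); k <- nrow(A2)
    D2 <- outer(rowSums(A2^2), rowSums(A1^2), "+") - 2 * A2 %*% t(A1)
    ## smooth distance floor: sqrt(d^2 + eps^2) stays close to d away
    ## from zero but is differentiable through d = 0, so exact matches
    ## neither blow up the loss nor pin the optimization at a kink
    Dc <- sqrt(pmax(D2, 0) + epsilon^2)
    dmin <- Dc[cbind(seq_len(k), max.col(-Dc, ties.method = "first"))]
    ratio <- Dc / dmin
    W <- ratio^gamma
    S <- rowMeans(W)
    lj <- dmin * S^(1 / gamma)
    perPoint[cl$j] <- lj
    loss <- loss + sum(lj)
    if (wantGrad) {
      A <- W / ratio^2
      coef <- S^((1 - gamma) / gamma) / (m * dmin)
      g <- coef * (rowSums(A) * A2 - A %*% A1)
      grad[cl$j, ] <- grad[cl$j, ] + g
    }
  }
  list(loss = loss, grad = grad, perPoint = perPoint)
}

#' Generalized-mean alignment loss
#'
#' For each unlabeled neuron, the power mean (exponent gamma < 0) of its
#' Euclidean distances to all labeled neurons of the same color, summed
#' over unlabeled neurons. Negative gamma weights the smallest distances
#' most; as gamma approaches -Inf the loss tends to the sum of per-point
#' minimum same-color distances, while finite gamma lets slightly farther
#' candidate partners still contribute gradient (which protects against
#' poor local minima early in the descent). Distances enter as
#' sqrt(d^2 + epsilon^2), a smooth floor keeping loss and gradient
#' finite and differentiable through d = 0.
#'
#' @param labeled reference positions: [NeuronPointCloud-class],
#'   [Atlas-class], or n x 3 matrix.
#' @param unlabeled query positions (same accepted types).
#' @param cfg a [GMConfig-class] from [gmConfig()].
#' @return non-negative scalar loss in micrometres. Errors when an
#'   unlabeled color has no same-color labeled neuron.
#' @examples
#' gmLoss(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))   # 5
#' @export
gmLoss <- function(labeled, unlabeled, cfg = gmConfig()) {
  P1 <- .coordsOf(labeled)
  P2 <- .coordsOf(unlabeled)
  .gmCore(P1, P2, .colorsOf(labeled), .colorsOf(unlabeled),
          cfg@gamma, cfg@epsilon)$loss
}

#' Apply a Gaussian-mixture deformation field
#'
#' Displaces each position r by the kernel-weighted sum of the field's
#' displacement vectors: r + sum_n d_n exp(-|r - (r_n + s)|^2 / (2
#' sigma^2)), where s is the global shift applied to the bump centers.
#'
#' @param params a [DeformationParams-class].
#' @param positions n x 3 matrix or [NeuronPointCloud-class].
#' @return displaced positions in the same form as supplied.
#' @export
deformationApply <- function(params, positions) {
  stopifnot(is(params, "DeformationParams"))
  validObject(params)
  asCloud <- is(positions, "NeuronPointCloud")
  P <- .coordsOf(positions)
  K <- .defKernel(P, params@centers, params@globalShift, params@sigma)$K
  out <- P + K %*% params@displacements
  if (asCloud) {
    res <- positions
    res@coords <- unname(out)
    colnames(res@coords) <- c("x", "y", "z")
    res
  } else out
}

.defKernel <- function(P, centers, shift, sigma) {
  C <- centers + matrix(shift, nrow(centers), 3, byrow = TRUE)
  Q <- outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C)
  Q <- pmax(Q, 0)
  list(K = exp(-Q / (2 * sigma^2)), Q = Q, C = C)
}

.descend <- function(theta, objgrad, cfg) {
  res <- objgrad(theta)
  trace <- res$loss
  for (it in seq_len(cfg@maxIters)) {
    if (!is.finite(res$loss))
      stop("loss diverged (non-finite) at iteration ", it)
    g <- res$grad
    step <- cfg@learningRate
    improved <- FALSE
    for (h in 1:40) {
      cand <- theta - step * g
      candRes <- objgrad(cand)
      if (is.finite(candRes$loss) && candRes$loss <= res$loss) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    relChange <- (res$loss - candRes$loss) / max(res$loss, cfg@epsilon)
    theta <- cand
    res <- candRes
    trace <- c(trace, res$loss)
    if (relChange <= cfg@tol) break
  }
  list(theta = theta, loss = res$loss, trace = trace)
}

#' Align an unlabeled cloud to an atlas by free-position descent
#'
#' Minimizes the generalized-mean loss by full-batch gradient descent
#' directly on the unlabeled positions, with backtracking line search
#' (the step is halved until the loss does not increase), so the loss
#' trace is monotonically non-increasing.
#'
#' @param unlabeled unlabeled [NeuronPointCloud-class].
#' @param atlas labeled reference: [Atlas-class] or
#'   [NeuronPointCloud-class].
#' @param cfg a [GMConfig-class].
#' @return list with \code{cloud} (transformed unlabeled cloud),
#'   \code{positions} (n x 3 matrix) and \code{trace} (loss per
#'   iteration, non-increasing).
#' @export
alignGM <- function(unlabeled, atlas, cfg = gmConfig()) {
  validObject(cfg)
  P1 <- .coordsOf(atlas)
  U <- .coordsOf(unlabeled)
  c1 <- .colorsOf(atlas)
  c2 <- .colorsOf(unlabeled)
  n2 <- nrow(U)
  objgrad <- function(theta) {
    X <- matrix(theta, n2, 3)
    r <- .gmCore(P1, X, c1, c2, cfg@gamma, cfg@epsilon, wantGrad = TRUE)
    list(loss = r$loss, grad = as.numeric(r$grad))
  }
  fit <- .descend(as.numeric(U), objgrad, cfg)
  X <- matrix(fit$theta, n2, 3)
  cloud <- if (is(unlabeled, "NeuronPointCloud")) {
    out <- unlabeled
    out@coords <- unname(X)
    colnames(out@coords) <- c("x", "y", "z")
    out
  } else pointCloud(X)
  list(cloud = cloud, positions = X, trace = fit$trace)
}

## evenly spaced grid of about nCenters points over the cloud's bounding
## box, axis counts proportional to the box edge lengths
.centerGrid <- function(P, nCenters) {
  lo <- apply(P, 2, min)
  hi <- apply(P, 2, max)
  L <- pmax(hi - lo, 1e-6)
  counts <- pmax(1L, round(L * (nCenters / prod(L))^(1 / 3)))
  ## adjust the largest axis to land near the requested count
  ax <- which.max(L)
  counts[ax] <- max(1L, round(nCenters / prod(counts[-ax])))
  gr <- lapply(1:3, function(a)
    if (counts[a] == 1L) (lo[a] + hi[a]) / 2
    else seq(lo[a], hi[a], length.out = counts[a]))
  as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
}

#' Align with a biologically realistic deformation parameterization
#'
#' Instead of moving every unlabeled neuron independently, the moving
#' positions are parameterized by a Gaussian-mixture deformation field
#' ([DeformationParams-class]): nearby neurons share displacement, which
#' restricts the search to smooth, tissue-like deformations. The field
#' parameters -- the shared influence radius sigma (in log space), the N
#' displacement vectors, the N bump centers, and the redundant global
#' shift -- are fitted by limited-memory quasi-Newton descent (L-BFGS-B)
#' on the analytic gradient of the generalized-mean loss; the 6N+4
#' parameter space couples every neuron through sigma, which plain
#' first-order steps traverse too slowly to localize the field.
#'
#' Initialization: bump centers on an even grid over the unlabeled
#' cloud's bounding box; sigma = 1/4 of the bounding-box diagonal;
#' displacements start either at zero or at a least-squares constant
#' field reproducing the atlas-minus-cloud centroid offset, whichever
#' gives the lower starting loss (the centroid candidate removes a rigid
#' offset immediately, but is counterproductive when the two clouds have
#' very different supports, e.g. a head cloud against a whole-body
#' atlas).
#'
#' @inheritParams alignGM
#' @param nCenters requested number of deformation centers (default 100;
#'   the grid uses the nearest feasible count).
#' @return list with \code{cloud}, \code{positions}, \code{params}
#'   (fitted [DeformationParams-class]) and \code{trace}.
#' @export
alignGMRealistic <- function(unlabeled, atlas, cfg = gmConfig(),
                             nCenters = 100L) {
  validObject(cfg)
  P1 <- .coordsOf(atlas)
  U <- .coordsOf(unlabeled)
  c1 <- .colorsOf(atlas)
  c2 <- .colorsOf(unlabeled)
  n2 <- nrow(U)
  centers0 <- .centerGrid(U, nCenters)
  N <- nrow(centers0)
  lo <- apply(U, 2, min); hi <- apply(U, 2, max)
  sigma0 <- max(sqrt(sum((hi - lo)^2)) / 4, 1e-3)
  unpack <- function(theta) {
    list(logSigma = theta[1],
         D = matrix(theta[1 + seq_len(3 * N)], N, 3),
         Cn = matrix(theta[1 + 3 * N + seq_len(3 * N)], N, 3),
         s = theta[2 + 6 * N + 0:2])
  }
  objgrad <- function(theta) {
    p <- unpack(theta)
    sigma <- exp(p$logSigma)
    kd <- .defKernel(U, p$Cn, p$s, sigma)
    X <- U + kd$K %*% p$D
    r <- .gmCore(P1, X, c1, c2, cfg@gamma, cfg@epsilon, wantGrad = TRUE)
    G <- r$grad
    gD <- t(kd$K) %*% G
    M <- G %*% t(p$D)          # n2 x N : G_j . d_n
    MK <- M * kd$K
    colMK <- colSums(MK)
    gC <- (t(MK) %*% U - colMK * kd$C) / sigma^2
    gS <- colSums(gC)
    gLogSigma <- sum(MK * kd$Q) / sigma^2
    list(loss = r$loss,
         grad = c(gLogSigma, as.numeric(gD), as.numeric(gC), gS))
  }
  ## initialization: zero field vs least-squares constant field matching
  ## the centroid offset; keep the better start
  K0 <- .defKernel(U, centers0, c(0, 0, 0), sigma0)$K
  kap <- rowSums(K0)
  v <- colMeans(P1) - colMeans(U)
  alpha <- sum(kap) / sum(kap^2)
  Dcand <- matrix(v * alpha, N, 3, byrow = TRUE)
  thetaZero <- c(log(sigma0), numeric(3 * N), as.numeric(centers0),
                 numeric(3))
  thetaCand <- c(log(sigma0), as.numeric(Dcand), as.numeric(centers0),
                 numeric(3))
  theta0 <- if (objgrad(thetaCand)$loss < objgrad(thetaZero)$loss)
    thetaCand else thetaZero
  trace <- numeric(0)
  fn <- function(theta) {
    v <- objgrad(theta)$loss
    if (!is.finite(v)) return(1e300)
    trace <<- c(trace, v)
    v
  }
  gr <- function(theta) objgrad(theta)$grad
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = cfg@maxIters,
                                     factr = max(cfg@tol / 1e-10, 10)))
  if (!is.finite(opt$value))
    stop("loss diverged (non-finite) during optimization")
  fit <- list(theta = opt$par)
  p <- unpack(fit$theta)
  params <- new("DeformationParams", sigma = exp(p$logSigma),
                displacements = p$D, centers = p$Cn, globalShift = p$s)
  X <- deformationApply(params, U)
  cloud <- if (is(unlabeled, "NeuronPointCloud")) {
    out <- unlabeled
    out@coords <- unname(X)
    colnames(out@coords) <- c("x", "y", "z")
    out
  } else pointCloud(X)
  ## best-so-far loss over objective evaluations (monotone by construction)
  list(cloud = cloud, positions = X, params = params,
       trace = cummin(trace))
}

#' Greedy color-constrained identity assignment
#'
#' From the matrix of pairwise Euclidean distances between transformed
#' unlabeled neurons and atlas entries, repeatedly picks the globally
#' smallest remaining element (ties broken by lowest row, then column),
#' assigns that identity, and removes the row and column, until no
#' admissible pair remains. When colors are available on both sides an
#' unlabeled neuron may only take the identity of a same-color atlas
#' entry.
#'
#' @param transformed aligned unlabeled positions
#'   ([NeuronPointCloud-class] or n x 3 matrix).
#' @param atlas labeled reference ([Atlas-class] or labeled
#'   [NeuronPointCloud-class]).
#' @return an [Assignment-class]; unlabeled neurons left over within an
#'   exhausted color class are reported in \code{unmatched}.
#' @export
assignIds <- function(transformed, atlas) {
  P2 <- .coordsOf(transformed)
  if (is(atlas, "Atlas")) atlas <- asPointCloud(atlas)
  stopifnot(is(atlas, "NeuronPointCloud"), length(neuronIds(atlas)) > 0)
  P1 <- coords(atlas)
  c1 <- .colorsOf(atlas)
  c2 <- .colorsOf(transformed)
  n2 <- nrow(P2); n1 <- nrow(P1)
  D2 <- outer(rowSums(P2^2), rowSums(P1^2), "+") - 2 * P2 %*% t(P1)
  D <- sqrt(pmax(D2, 0))
  if (!is.null(c1) && !is.null(c2))
    D[outer(c2, c1, "!=")] <- Inf
  idx <- integer(0); nm <- character(0); dd <- numeric(0)
  repeat {
    mn <- suppressWarnings(min(D))
    if (!is.finite(mn)) break
    cand <- which(D == mn, arr.ind = TRUE)
    pick <- cand[order(cand[, 1], cand[, 2])[1], ]
    idx <- c(idx, pick[1])
    nm <- c(nm, neuronIds(atlas)[pick[2]])
    dd <- c(dd, mn)
    D[pick[1], ] <- Inf
    D[, pick[2]] <- Inf
  }
  new("Assignment", index = as.integer(idx), name = nm, distance = dd,
      unmatched = setdiff(seq_len(n2), idx))
}
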