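#' @include gm-align.R
NULL

#' BioNoiseSpec: settings for simulated biological deformation noise
#'
#' @slot nCenters number of random deformation centers (default 100).
#' @slot amplitude displacement magnitude |d_n| in micrometres
#'   (default 6.1).
#' @slot sigma influence radius of each center, micrometres.
#' @slot seed integer seed.
#' @slot gaussianMagnitude if TRUE, draw each displacement from an
#'   isotropic 3D Gaussian of standard deviation sigma instead of using
#'   a fixed magnitude with random direction.
#' @seealso [bioNoiseSpec()], [bioNoise()]
#' @export
setClass("BioNoiseSpec",
  representation(nCenters = "integer", amplitude = "numeric",
                 sigma = "numeric", seed = "integer",
                 gaussianMagnitude = "logical"))

setValidity("BioNoiseSpec", function(object) {
  msgs <- character(0)
  if (object@nCenters < 1L) msgs <- c(msgs, "nCenters must be >= 1")
  if (object@amplitude < 0) msgs <- c(msgs, "amplitude must be >= 0")
  if (object@sigma <= 0) msgs <- c(msgs, "sigma must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname BioNoiseSpec-class
#' @param nCenters,amplitude,sigma,seed,gaussianMagnitude see slots
#' @export
bioNoiseSpec <- function(nCenters = 100L, amplitude = 6.1, sigma = 20,
                         seed = 0L, gaussianMagnitude = FALSE) {
  new("BioNoiseSpec", nCenters = as.integer(nCenters),
      amplitude = as.numeric(amplitude), sigma = as.numeric(sigma),
      seed = as.integer(seed),
      gaussianMagnitude = as.logical(gaussianMagnitude))
}

.withCoords <- function(cloud, newCoords) {
  out <- cloud
  out@coords <- unname(as.matrix(newCoords))
  colnames(out@coords) <- c("x", "y", "z")
  out
}

#' Rigid group jitter
#'
#' Adds one shared random translation to every neuron, each component
#' drawn uniformly on [-maxShift, +maxShift] micrometres.
#'
#' @param cloud a [NeuronPointCloud-class].
#' @param maxShift per-axis bound in micrometres (default 5).
#' @param seed integer seed.
#' @return list with \code{cloud} (shifted) and \code{shift} (the true
#'   3-vector, for ground truth).
#' @export
rigidJitter <- function(cloud, maxShift = 5, seed = 0L) {
  stopifnot(maxShift >= 0)
  shift <- withr::with_seed(seed, stats::runif(3, -maxShift, maxShift))
  list(cloud = .withCoords(cloud,
         sweep(coords(cloud), 2, shift, "+")),
       shift = shift)
}

#' Crop a cloud along one axis
#'
#' Retains, in order, the records whose chosen coordinate lies in
#' [lo, hi].
#'
#' @param cloud a [NeuronPointCloud-class].
#' @param axis one of "x", "y", "z".
#' @param lo,hi inclusive bounds in micrometres (lo < hi).
#' @return the cropped cloud; a warning is issued when nothing survives.
#' @export
cropCloud <- function(cloud, axis = c("x", "y", "z"), lo = -Inf, hi = Inf) {
  axis <- match.arg(axis)
  stopifnot(lo < hi)
  v <- coords(cloud)[, match(axis, c("x", "y", "z"))]
  keep <- which(v >= lo & v <= hi)
  if (!length(keep)) warning("crop removed every neuron")
  cloud[keep]
}

#' Random neuron dropout
#'
#' Removes \code{nRemove} neurons chosen uniformly without replacement;
#' the survivors keep their original order.
#'
#' @param cloud a [NeuronPointCloud-class].
#' @param nRemove number of neurons to remove (0..n).
#' @param seed integer seed.
#' @return list with \code{cloud} (reduced), \code{removed} (indices)
#'   and \code{removedNames} (names, when the cloud is labeled).
#' @export
dropoutNeurons <- function(cloud, nRemove, seed = 0L) {
  n <- nNeurons(cloud)
  if (nRemove < 0 || nRemove > n)
    stop("nRemove must be between 0 and ", n)
  removed <- if (nRemove == 0L) integer(0)
             else withr::with_seed(seed, sort(sample.int(n, nRemove)))
  keep <- setdiff(seq_len(n), removed)
  list(cloud = cloud[keep], removed = removed,
       removedNames = if (length(cloud@ids)) cloud@ids[removed]
                      else character(0))
}

#' Simulated biological deformation noise
#'
#' Draws N deformation centers uniformly within the cloud's axis-aligned
#' bounding box and a displacement vector per center (random isotropic
#' direction with fixed magnitude \code{amplitude}, or a 3D Gaussian
#' draw when \code{gaussianMagnitude}), then displaces every neuron by
#' the resulting Gaussian-mixture field.
#'
#' @param cloud a [NeuronPointCloud-class].
#' @param spec a [BioNoiseSpec-class].
#' @return list with \code{cloud} (deformed) and \code{params} (the
#'   ground-truth [DeformationParams-class]).
#' @export
bioNoise <- function(cloud, spec = bioNoiseSpec()) {
  validObject(spec)
  P <- coords(cloud)
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  N <- spec@nCenters
  draws <- withr::with_seed(spec@seed, {
    centers <- cbind(stats::runif(N, lo[1], hi[1]),
                     stats::runif(N, lo[2], hi[2]),
                     stats::runif(N, lo[3], hi[3]))
    raw <- matrix(stats::rnorm(3 * N), N, 3)
    list(centers = centers, raw = raw)
  })
  disp <- if (spec@gaussianMagnitude) {
    draws$raw * spec@sigma
  } else {
    dir <- draws$raw / sqrt(rowSums(draws$raw^2))
    dir * spec@amplitude
  }
  params <- new("DeformationParams", sigma = spec@sigma,
                displacements = disp, centers = draws$centers,
                globalShift = c(0, 0, 0))
  list(cloud = deformationApply(params, cloud), params = params)
}

#' Assign randomized colors consistently to two labeled clouds
#'
#' Each neuron NAME present in both clouds gets a color drawn uniformly
#' from {0, ..., k-1}; the same name receives the same color in both
#' clouds. With \code{unique = TRUE} (requires k >= number of names) the
#' colors are a random injection, so every neuron has a distinct color.
#'
#' @param cloudA,cloudB labeled clouds over the same name set.
#' @param k number of colors (>= 1).
#' @param seed integer seed.
#' @param unique force all-distinct colors.
#' @return list with recolored \code{cloudA} and \code{cloudB}.
#' @export
assignRandomColors <- function(cloudA, cloudB, k, seed = 0L,
                               unique = FALSE) {
  stopifnot(k >= 1)
  na <- neuronIds(cloudA); nb <- neuronIds(cloudB)
  if (!length(na) || !length(nb) || !setequal(na, nb))
    stop("clouds must be labeled over the same name set")
  nms <- sort(na)
  cols <- withr::with_seed(seed, {
    if (unique) {
      if (k < length(nms)) stop("unique colors require k >= n")
      sample.int(k, length(nms)) - 1L
    } else {
      sample.int(k, length(nms), replace = TRUE) - 1L
    }
  })
  names(cols) <- nms
  outA <- cloudA; outA@colors <- unname(cols[na])
  outB <- cloudB; outB@colors <- unname(cols[nb])
  list(cloudA = outA, cloudB = outB)
}
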