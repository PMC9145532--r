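#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' NeuronPointCloud: an ordered set of neuron positions
#'
#' Container for one worm's neuron point cloud: an ordered set of 3D
#' positions in micrometres, optionally carrying per-neuron names
#' (identities) and discrete color indices (e.g. NeuroPAL barcode classes).
#' The \code{frameTag} records whether positions are in the raw imaging
#' frame or in the canonical straightened frame.
#'
#' @slot coords numeric matrix, one row per neuron, columns \code{x,y,z}
#'   (micrometres).
#' @slot ids character vector of neuron names (length \code{nrow(coords)}),
#'   or \code{character(0)} for an unlabeled cloud. Names must be unique.
#' @slot colors integer vector of non-negative color indices (length
#'   \code{nrow(coords)}), or \code{integer(0)} for a colorless cloud.
#' @slot frameTag either \code{"raw"} or \code{"canonical"}.
#'
#' @seealso [pointCloud()], [readPointCloud()], [writePointCloud()]
#' @export
setClass("NeuronPointCloud",
  representation(
    coords   = "matrix",
    ids      = "character",
    colors   = "integer",
    frameTag = "character"
  ),
  prototype(
    coords   = matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z"))),
    ids      = character(0),
    colors   = integer(0),
    frameTag = "raw"
  )
)

setValidity("NeuronPointCloud", function(object) {
  msgs <- character(0)
  cc <- object@coords
  if (!is.numeric(cc) || ncol(cc) != 3L)
    msgs <- c(msgs, "coords must be a numeric matrix with 3 columns (x, y, z)")
  else if (nrow(cc) > 0 && !all(is.finite(cc)))
    msgs <- c(msgs, "all coordinates must be finite")
  n <- nrow(cc)
  if (length(object@ids) != 0L && length(object@ids) != n)
    msgs <- c(msgs, "ids must be empty or have one entry per neuron")
  if (length(object@ids) > 0L && anyDuplicated(object@ids))
    msgs <- c(msgs, sprintf("duplicate neuron names: %s",
      paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  if (length(object@colors) != 0L && length(object@colors) != n)
    msgs <- c(msgs, "colors must be empty or defined for every neuron")
  if (length(object@colors) > 0L &&
      (anyNA(object@colors) || any(object@colors < 0L)))
    msgs <- c(msgs, "color indices must be non-negative integers")
  if (!(length(object@frameTag) == 1L &&
        object@frameTag %in% c("raw", "canonical")))
    msgs <- c(msgs, "frameTag must be \"raw\" or \"canonical\"")
  if (length(msgs)) msgs else TRUE
})

#' HullMask: a binary 2D worm-body mask
#'
#' The binarized largest-area z-slice of a worm image stack. The foreground
#' is required to be a single connected component that does not touch the
#' raster border, so that a closed body outline can be traced at sub-pixel
#' precision.
#'
#' @slot grid logical matrix; \code{TRUE} = inside the worm. Rows index y
#'   (increasing downward in image convention), columns index x.
#' @slot pixelSize micrometres per pixel, isotropic.
#'
#' @seealso [readHullMask()], [extractBoundary()]
#' @export
setClass("HullMask",
  representation(grid = "matrix", pixelSize = "numeric"))

setValidity("HullMask", function(object) {
  msgs <- character(0)
  g <- object@grid
  if (!is.logical(g)) msgs <- c(msgs, "grid must be a logical matrix")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a single positive number")
  if (is.logical(g)) {
    if (!any(g)) msgs <- c(msgs, "mask has empty foreground")
    else {
      if (any(g[1, ]) || any(g[nrow(g), ]) || any(g[, 1]) || any(g[, ncol(g)]))
        msgs <- c(msgs,
          "foreground touches the raster border; pad the image first")
      if (.countComponents(g) != 1L)
        msgs <- c(msgs, "foreground must be a single connected component")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CircleChain: the inscribed tangent circles of a worm hull
#'
#' The ordered family of circles inscribed in the worm hull, each tangent
#' to both body edges. Centers trace the body midline; the cumulative arc
#' length along the center polyline is the canonical anterior-posterior
#' coordinate before the final isotropic rescale.
#'
#' @slot centers numeric matrix (k x 2) of circle centers, micrometres.
#' @slot radii numeric vector of circle radii (> 0), micrometres.
#' @slot s numeric vector: edge-curve parameter of each circle, in [0, 1],
#'   strictly increasing.
#' @slot cumLength cumulative midline arc length at each center, starting
#'   at 0, micrometres.
#' @export
setClass("CircleChain",
  representation(centers = "matrix", radii = "numeric",
                 s = "numeric", cumLength = "numeric"))

setValidity("CircleChain", function(object) {
  msgs <- character(0)
  k <- nrow(object@centers)
  if (ncol(object@centers) != 2L)
    msgs <- c(msgs, "centers must have 2 columns")
  if (length(object@radii) != k || length(object@s) != k ||
      length(object@cumLength) != k)
    msgs <- c(msgs, "radii, s and cumLength must match the number of centers")
  if (k > 0) {
    if (any(object@radii <= 0)) msgs <- c(msgs, "all radii must be positive")
    if (is.unsorted(object@s, strictly = TRUE))
      msgs <- c(msgs, "s must be strictly increasing")
    if (is.unsorted(object@cumLength))
      msgs <- c(msgs, "cumLength must be non-decreasing")
    if (abs(object@cumLength[1]) > 1e-9)
      msgs <- c(msgs, "cumLength must start at 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' CanonicalTransform: a reusable worm-straightening map
#'
#' The straightening map produced by [canonicalizeWorm()]: the inscribed
#' circle chain, the per-circle rigid xy maps implied by it, and the final
#' isotropic scale taking the midline to the canonical extent.
#'
#' @slot chain the [CircleChain-class] the map is built from.
#' @slot scale the final isotropic scale factor (applied to x, y and z).
#' @slot targetExtent numeric(2): canonical x-range after rescale,
#'   micrometres (default c(0, 800)).
#' @slot flipAP logical; if TRUE the anterior-posterior axis is flipped so
#'   the first chain endpoint maps to the high-x end.
#' @export
setClass("CanonicalTransform",
  representation(chain = "CircleChain", scale = "numeric",
                 targetExtent = "numeric", flipAP = "logical"))

setValidity("CanonicalTransform", function(object) {
  msgs <- character(0)
  if (length(object@scale) != 1L || object@scale <= 0)
    msgs <- c(msgs, "scale must be a single positive number")
  if (length(object@targetExtent) != 2L ||
      object@targetExtent[2] <= object@targetExtent[1])
    msgs <- c(msgs, "targetExtent must be an increasing range")
  if (length(object@flipAP) != 1L) msgs <- c(msgs, "flipAP must be TRUE/FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Atlas: named canonical neuron positions with spread statistics
#'
#' A positional atlas: for each named neuron, the canonical 3D position
#' (componentwise median over contributing worms), a per-axis spread
#' (median absolute deviation), the number of contributing worms, and an
#' optional color index.
#'
#' @slot positions numeric matrix (m x 3), micrometres, canonical frame.
#' @slot ids character vector of unique neuron names.
#' @slot spread numeric matrix (m x 3) of per-axis spreads (MAD), or a
#'   0-row matrix when unavailable.
#' @slot colors integer vector of color indices, or \code{integer(0)}.
#' @slot counts integer vector: contributing-worm count per entry.
#' @slot extent numeric(2): the canonical x-range, micrometres.
#' @seealso [buildAtlas()], [mergeSubatlas()], [readAtlas()]
#' @export
setClass("Atlas",
  representation(positions = "matrix", ids = "character", spread = "matrix",
                 colors = "integer", counts = "integer", extent = "numeric"))

setValidity("Atlas", function(object) {
  msgs <- character(0)
  m <- nrow(object@positions)
  if (ncol(object@positions) != 3L)
    msgs <- c(msgs, "positions must have 3 columns")
  if (length(object@ids) != m) msgs <- c(msgs, "one name per entry required")
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "atlas names must be unique")
  if (nrow(object@spread) != 0L && nrow(object@spread) != m)
    msgs <- c(msgs, "spread must be empty or one row per entry")
  if (length(object@colors) != 0L && length(object@colors) != m)
    msgs <- c(msgs, "colors must be empty or one per entry")
  if (length(object@counts) != m)
    msgs <- c(msgs, "counts must have one value per entry")
  if (length(object@extent) != 2L || object@extent[2] <= object@extent[1])
    msgs <- c(msgs, "extent must be an increasing range")
  if (length(msgs)) msgs else TRUE
})

#' DeformationParams: a Gaussian-mixture deformation field
#'
#' Parameters of a smooth displacement field modeling coherent
#' inter-individual tissue deformation: N Gaussian bumps with shared
#' influence radius sigma, each carrying its own displacement vector.
#' A point r is displaced by the kernel-weighted sum of the displacement
#' vectors; the global shift is a redundant translation added to the bump
#' centers for numerical stability of the optimization.
#'
#' @slot sigma influence radius, micrometres (> 0), shared by all bumps.
#' @slot displacements numeric matrix (N x 3) of displacement vectors, um.
#' @slot centers numeric matrix (N x 3) of bump centers, micrometres.
#' @slot globalShift numeric(3): translation added to all centers, um.
#' @seealso [deformationApply()], [alignGMRealistic()], [bioNoise()]
#' @export
setClass("DeformationParams",
  representation(sigma = "numeric", displacements = "matrix",
                 centers = "matrix", globalShift = "numeric"))

setValidity("DeformationParams", function(object) {
  msgs <- character(0)
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    msgs <- c(msgs, "sigma must be a single positive number")
  if (ncol(object@displacements) != 3L || ncol(object@centers) != 3L)
    msgs <- c(msgs, "displacements and centers must have 3 columns")
  if (nrow(object@displacements) != nrow(object@centers))
    msgs <- c(msgs, "one displacement vector per center required")
  if (length(object@globalShift) != 3L)
    msgs <- c(msgs, "globalShift must be a 3-vector")
  if (length(msgs)) msgs else TRUE
})

#' GMConfig: settings for generalized-mean alignment
#'
#' @slot gamma power-mean exponent, negative in normal use (gamma = -6
#'   balances sharp pairing against gradient flow from slightly farther
#'   candidates); positive values are admitted for diagnostics such as
#'   the gamma = 2 Gaussian-mixture correspondence.
#' @slot epsilon distance floor in micrometres; distances enter the loss
#'   as sqrt(d^2 + epsilon^2) so it stays finite and smooth for gamma < 0.
#' @slot learningRate initial gradient-descent step size (micrometre scale).
#' @slot maxIters maximum number of descent iterations (>= 1).
#' @slot tol relative loss-change convergence threshold.
#' @slot seed integer seed for any stochastic initialization.
#' @seealso [gmConfig()], [alignGM()], [alignGMRealistic()]
#' @export
setClass("GMConfig",
  representation(gamma = "numeric", epsilon = "numeric",
                 learningRate = "numeric", maxIters = "integer",
                 tol = "numeric", seed = "integer"))

setValidity("GMConfig", function(object) {
  msgs <- character(0)
  if (object@gamma == 0) msgs <- c(msgs, "gamma must be non-zero")
  if (object@epsilon <= 0) msgs <- c(msgs, "epsilon must be positive")
  if (object@maxIters < 1L) msgs <- c(msgs, "maxIters must be >= 1")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@tol <= 0) msgs <- c(msgs, "tol must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Assignment: unlabeled-neuron identities
#'
#' The result of greedy color-constrained matching: for each matched
#' unlabeled neuron, the assigned atlas name and the Euclidean match
#' distance; unmatched indices (when the clouds differ in size within a
#' color class) are listed separately.
#'
#' @slot index integer indices into the unlabeled cloud (matched rows).
#' @slot name character: assigned atlas names (parallel to index).
#' @slot distance numeric: match distances, micrometres.
#' @slot unmatched integer indices of unlabeled neurons left unassigned.
#' @seealso [assignIds()], [accuracy()]
#' @export
setClass("Assignment",
  representation(index = "integer", name = "character",
                 distance = "numeric", unmatched = "integer"))

setValidity("Assignment", function(object) {
  msgs <- character(0)
  k <- length(object@index)
  if (length(object@name) != k || length(object@distance) != k)
    msgs <- c(msgs, "index, name and distance must have equal length")
  if (anyDuplicated(object@name))
    msgs <- c(msgs, "each atlas name may be assigned at most once")
  if (anyDuplicated(c(object@index, object@unmatched)))
    msgs <- c(msgs, "each unlabeled index may appear at most once")
  if (length(msgs)) msgs else TRUE
})
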