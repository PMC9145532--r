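#' @include AllGenerics.R
NULL

#' Construct a NeuronPointCloud
#'
#' @param coords numeric matrix or data frame with 3 columns (x, y, z),
#'   micrometres.
#' @param ids optional character vector of unique neuron names.
#' @param colors optional integer vector of non-negative color indices.
#' @param frameTag \code{"raw"} (default) or \code{"canonical"}.
#' @return a [NeuronPointCloud-class]
#' @examples
#' pc <- pointCloud(cbind(x = 1:3, y = 0, z = 0), ids = c("A", "B", "C"))
#' nNeurons(pc)
#' @export
pointCloud <- function(coords, ids = NULL, colors = NULL, frameTag = "raw") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have exactly 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  rownames(coords) <- NULL
  new("NeuronPointCloud",
      coords = coords,
      ids = if (is.null(ids)) character(0) else as.character(ids),
      colors = if (is.null(colors)) integer(0) else as.integer(colors),
      frameTag = frameTag)
}

#' @rdname NeuronPointCloud-class
#' @export
setMethod("nNeurons", "NeuronPointCloud", function(x) nrow(x@coords))

#' @rdname NeuronPointCloud-class
#' @export
setMethod("coords", "NeuronPointCloud", function(x) x@coords)

#' @rdname NeuronPointCloud-class
#' @export
setMethod("neuronIds", "NeuronPointCloud", function(x) x@ids)

#' @rdname NeuronPointCloud-class
#' @export
setMethod("neuronColors", "NeuronPointCloud", function(x) x@colors)

#' @rdname NeuronPointCloud-class
#' @export
setMethod("frameTag", "NeuronPointCloud", function(x) x@frameTag)

#' @rdname NeuronPointCloud-class
#' @export
setReplaceMethod("neuronColors", "NeuronPointCloud", function(x, value) {
  x@colors <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(x)
  x
})

#' @rdname NeuronPointCloud-class
#' @param i index vector for subsetting
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "NeuronPointCloud", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nNeurons(x))[i]
  new("NeuronPointCloud",
      coords = x@coords[idx, , drop = FALSE],
      ids = if (length(x@ids)) x@ids[idx] else character(0),
      colors = if (length(x@colors)) x@colors[idx] else integer(0),
      frameTag = x@frameTag)
})

setMethod("show", "NeuronPointCloud", function(object) {
  cat(sprintf("NeuronPointCloud: %d neurons [%s frame]%s%s\n",
    nNeurons(object), object@frameTag,
    if (length(object@ids)) ", labeled" else ", unlabeled",
    if (length(object@colors))
      sprintf(", %d colors", length(unique(object@colors))) else ""))
  if (nNeurons(object) > 0) {
    rng <- apply(object@coords, 2, range)
    cat(sprintf("  extent: x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] um\n",
      rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(NULL)
})

setMethod("show", "HullMask", function(object) {
  cat(sprintf("HullMask: %d x %d pixels at %.3g um/px, %d foreground px\n",
    nrow(object@grid), ncol(object@grid), object@pixelSize,
    sum(object@grid)))
  invisible(NULL)
})

setMethod("show", "CircleChain", function(object) {
  k <- length(object@radii)
  cat(sprintf("CircleChain: %d circles, midline length %.2f um, radii [%.2f, %.2f] um\n",
    k, if (k) object@cumLength[k] else 0,
    if (k) min(object@radii) else NA, if (k) max(object@radii) else NA))
  invisible(NULL)
})

setMethod("show", "Atlas", function(object) {
  cat(sprintf("Atlas: %d entries, extent [%.0f, %.0f] um%s%s\n",
    length(object@ids), object@extent[1], object@extent[2],
    if (nrow(object@spread)) ", with spread" else "",
    if (length(object@colors)) ", colored" else ""))
  invisible(NULL)
})

setMethod("show", "DeformationParams", function(object) {
  cat(sprintf("DeformationParams: %d centers, sigma %.2f um, max |d| %.3f um\n",
    nrow(object@centers), object@sigma,
    if (nrow(object@displacements))
      max(sqrt(rowSums(object@displacements^2))) else 0))
  invisible(NULL)
})

setMethod("show", "Assignment", function(object) {
  cat(sprintf("Assignment: %d matched, %d unmatched\n",
    length(object@index), length(object@unmatched)))
  invisible(NULL)
})

#' @rdname Assignment-class
#' @param x an \code{Assignment}
#' @param ... ignored
#' @return data.frame with columns unlabeled_index, assigned_name,
#'   distance_um (matched pairs, in unlabeled-index order)
#' @export
as.data.frame.Assignment <- function(x, ...) {
  ord <- order(x@index)
  data.frame(unlabeled_index = x@index[ord],
             assigned_name = x@name[ord],
             distance_um = x@distance[ord],
             stringsAsFactors = FALSE)
}

#' Settings for generalized-mean alignment
#'
#' @param gamma negative power-mean exponent (default -6).
#' @param epsilon distance floor, micrometres (default 1e-3). With
#'   gamma < 0 a vanishing pairwise distance would make the loss and its
#'   gradient blow up; distances enter the loss as sqrt(d^2 + epsilon^2),
#'   a smooth floor that leaves distances above a few epsilon untouched.
#' @param learningRate initial step size for backtracking gradient
#'   descent (default 1, micrometre scale).
#' @param maxIters maximum descent iterations (default 500).
#' @param tol relative loss-change convergence threshold (default 1e-6).
#' @param seed integer seed for stochastic initialization (default 0).
#' @return a [GMConfig-class]
#' @export
gmConfig <- function(gamma = -6, epsilon = 1e-3, learningRate = 1,
                     maxIters = 500L, tol = 1e-6, seed = 0L) {
  new("GMConfig", gamma = as.numeric(gamma), epsilon = as.numeric(epsilon),
      learningRate = as.numeric(learningRate),
      maxIters = as.integer(maxIters), tol = as.numeric(tol),
      seed = as.integer(seed))
}
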