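#' @include io.R
NULL

#' Build a positional atlas from canonicalized labeled clouds
#'
#' Pools canonical-frame labeled clouds from multiple worms. For every
#' neuron name seen in at least \code{minCount} clouds, the atlas position
#' is the componentwise median over contributing worms (robust to outliers
#' and resistant to overall shrinking) and the per-axis spread is the
#' median absolute deviation (constant 1.4826, the usual consistency
#' scaling).
#'
#' @param clouds list of canonical labeled [NeuronPointCloud-class]
#'   objects; within each cloud every name appears at most once.
#' @param minCount minimum number of contributing worms for an entry to
#'   be kept (default 1).
#' @param extent canonical x-range recorded on the atlas (default
#'   c(0, 800) um).
#' @return an [Atlas-class]; errors on empty input or on conflicting
#'   color indices for the same name.
#' @examples
#' pc <- pointCloud(cbind(x = c(0, 10), y = 0, z = 0), ids = c("A", "B"),
#'                  frameTag = "canonical")
#' buildAtlas(list(pc, pc, pc))
#' @export
buildAtlas <- function(clouds, minCount = 1L, extent = c(0, 800)) {
  if (!length(clouds)) stop("need at least one cloud")
  for (cl in clouds) {
    stopifnot(is(cl, "NeuronPointCloud"))
    if (!length(cl@ids)) stop("all clouds must be labeled")
    if (cl@frameTag != "canonical")
      stop("all clouds must be in the canonical frame")
  }
  allNames <- sort(unique(unlist(lapply(clouds, neuronIds))))
  pos <- matrix(NA_real_, length(allNames), 3,
                dimnames = list(allNames, c("x", "y", "z")))
  spread <- pos
  counts <- integer(length(allNames))
  colorOf <- rep(NA_integer_, length(allNames))
  names(colorOf) <- allNames
  for (i in seq_along(allNames)) {
    nm <- allNames[i]
    rows <- lapply(clouds, function(cl) {
      k <- match(nm, cl@ids)
      if (is.na(k)) return(NULL)
      list(p = cl@coords[k, ],
           col = if (length(cl@colors)) cl@colors[k] else NA_integer_)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    P <- do.call(rbind, lapply(rows, `[[`, "p"))
    cols <- vapply(rows, `[[`, integer(1), "col")
    cols <- cols[!is.na(cols)]
    if (length(unique(cols)) > 1L)
      stop("conflicting color indices for neuron ", nm)
    if (length(cols)) colorOf[i] <- cols[1]
    pos[i, ] <- apply(P, 2, stats::median)
    spread[i, ] <- apply(P, 2, stats::mad)
    counts[i] <- nrow(P)
  }
  keep <- counts >= minCount
  hasColors <- !all(is.na(colorOf[keep]))
  if (hasColors && anyNA(colorOf[keep]))
    stop("color indices defined for some atlas entries but not all")
  posOut <- pos[keep, , drop = FALSE]
  spreadOut <- spread[keep, , drop = FALSE]
  rownames(posOut) <- NULL
  rownames(spreadOut) <- NULL
  new("Atlas",
      positions = posOut,
      ids = allNames[keep],
      spread = spreadOut,
      colors = if (hasColors) unname(colorOf[keep]) else integer(0),
      counts = counts[keep],
      extent = as.numeric(extent))
}

## Kabsch: least-squares rigid transform (rotation + translation, no
## scale) mapping rows of A onto rows of B, with reflection guard
.kabsch <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

#' Merge a high-resolution sub-atlas into a whole-body atlas
#'
#' Rigidly aligns a sub-atlas (e.g. a head or tail atlas built from
#' higher-resolution data) into the whole-body frame using the neurons
#' shared between the two within the stated region, then replaces the
#' region entries of the whole atlas by the transformed sub-atlas
#' positions. Entries outside the region are left bitwise unchanged.
#'
#' @param whole the whole-body [Atlas-class].
#' @param sub the sub-atlas to merge in.
#' @param region character vector of neuron names defining the region.
#' @return merged [Atlas-class]. Errors when fewer than 3 region names
#'   are shared, or when the shared points are collinear (the rigid
#'   transform is then underdetermined).
#' @export
mergeSubatlas <- function(whole, sub, region) {
  stopifnot(is(whole, "Atlas"), is(sub, "Atlas"))
  shared <- intersect(intersect(region, whole@ids), sub@ids)
  if (length(shared) < 3L)
    stop("need at least 3 shared neuron names in the region, got ",
         length(shared))
  A <- sub@positions[match(shared, sub@ids), , drop = FALSE]
  B <- whole@positions[match(shared, whole@ids), , drop = FALSE]
  ## collinearity check on the sub points
  Ac <- sweep(A, 2, colMeans(A))
  if (svd(Ac)$d[2] < 1e-9 * max(svd(Ac)$d[1], 1))
    stop("shared neurons are collinear; rigid transform underdetermined")
  tf <- .kabsch(A, B)
  replace <- intersect(region, intersect(whole@ids, sub@ids))
  out <- whole
  wi <- match(replace, whole@ids)
  si <- match(replace, sub@ids)
  out@positions[wi, ] <- t(tf$R %*% t(sub@positions[si, , drop = FALSE])) +
    matrix(tf$t, length(wi), 3, byrow = TRUE)
  if (nrow(whole@spread) && nrow(sub@spread))
    out@spread[wi, ] <- sub@spread[si, , drop = FALSE]
  out
}
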