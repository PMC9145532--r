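#' @include perturb.R
NULL

## class/member table for the adult hermaphrodite nervous system;
## 302 names in total, CAN L/R excluded on request
.neuronClassTable <- function() {
  lr <- c("ADA", "ADE", "ADF", "ADL", "AFD", "AIA", "AIB", "AIM", "AIN",
          "AIY", "AIZ", "ALM", "ALN", "ASE", "ASG", "ASH", "ASI", "ASJ",
          "ASK", "AUA", "AVA", "AVB", "AVD", "AVE", "AVF", "AVH", "AVJ",
          "AVK", "AWA", "AWB", "AWC", "BAG", "BDU", "CAN", "FLP", "HSN",
          "LUA", "NSM", "OLL", "PDE", "PHA", "PHB", "PHC", "PLM", "PLN",
          "PVC", "PVD", "PVN", "PVP", "PVQ", "PVW", "RIA", "RIB", "RIC",
          "RIF", "RIG", "RIM", "RIP", "RIV", "RMF", "RMG", "RMH", "SDQ",
          "URB", "URX", "I1", "I2", "M2", "M3", "MC")
  single <- c("ALA", "AQR", "AVG", "AVL", "AVM", "DVA", "DVB", "DVC",
              "I3", "I4", "I5", "I6", "M1", "M4", "M5", "MI", "PDA",
              "PDB", "PQR", "PVM", "PVR", "PVT", "RID", "RIH", "RIR",
              "RIS")
  quad <- c("CEP", "OLQ", "SAA", "SIA", "SIB", "SMB", "SMD", "URA", "URY")
  six <- c("IL1", "IL2", "RMD")
  vnc <- c(AS = 11L, DA = 9L, DB = 7L, DD = 6L, VA = 12L, VB = 11L,
           VC = 6L, VD = 13L)
  c(paste0(rep(lr, each = 2), c("L", "R")),
    single,
    paste0(rep(quad, each = 4), c("DL", "DR", "VL", "VR")),
    paste0(rep(six, each = 6), c("L", "R", "DL", "DR", "VL", "VR")),
    paste0("RME", c("D", "L", "R", "V")),
    paste0("SAB", c("D", "VL", "VR")),
    unlist(lapply(names(vnc), function(cl) paste0(cl, seq_len(vnc[[cl]]))),
           use.names = FALSE))
}

#' Adult hermaphrodite neuron names
#'
#' The 302 neuron names of the adult hermaphrodite nervous system,
#' generated from the standard class/member table. CAN L/R are excluded
#' by default (no panneuronal marker used for identification expresses
#' in CAN, so atlases built from such strains carry 300 neurons).
#'
#' @param excludeCAN drop CANL and CANR (default TRUE).
#' @return character vector of 300 (or 302) unique names, sorted.
#' @examples
#' length(neuronNames())        # 300
#' length(neuronNames(FALSE))   # 302
#' @export
neuronNames <- function(excludeCAN = TRUE) {
  nms <- .neuronClassTable()
  stopifnot(length(nms) == 302L, !anyDuplicated(nms))
  if (excludeCAN) nms <- setdiff(nms, c("CANL", "CANR"))
  sort(nms)
}

## constant-speed spine: arc length a in [0, L]; straight when
## bendAngle = 0, else a circular arc turning by bendAngle in total
.spineFun <- function(bodyLength, bendAngle) {
  if (abs(bendAngle) < 1e-9) {
    list(pos = function(a) cbind(a, 0 * a),
         normal = function(a) cbind(0 * a, 1 + 0 * a))
  } else {
    R <- bodyLength / abs(bendAngle)
    sgn <- sign(bendAngle)
    list(pos = function(a) {
           phi <- a / R
           cbind(R * sin(phi), sgn * R * (1 - cos(phi)))
         },
         normal = function(a) {
           phi <- a / R
           ## left-hand normal of the tangent (cos, sgn*sin)
           cbind(-sgn * sin(phi), cos(phi))
         })
  }
}

#' Generate a synthetic bent-worm fixture with analytic ground truth
#'
#' Builds a worm-shaped binary mask as the union of discs along a
#' constant-speed spine (straight or circular-arc bent), places neurons
#' inside the tube densely in the head and tail and sparsely in the
#' midbody, and returns the raw point cloud together with the analytic
#' canonical positions. For a constant-width worm the inscribed-circle
#' midline coincides with the spine between the two end caps, so the
#' ground-truth canonical position of a neuron at spine arc length a
#' with perpendicular offset (v, z) is ((a - h) * c, v * c, z * c) with
#' h the half-width and c = extent / (L - 2h).
#'
#' @param bodyLength spine length L in micrometres (default 1000).
#' @param halfWidth tube half-width h in micrometres (default 40).
#' @param taper fractional linear width reduction toward the tail
#'   (default 0 = constant width; ground truth is exact only for 0).
#' @param bendAngle total spine turning angle in radians (0 = straight,
#'   pi = U-bend). The bend radius L/|bendAngle| must exceed the width.
#' @param nNeurons number of neurons (default 300).
#' @param names neuron names (default [neuronNames()]); NULL for an
#'   unlabeled cloud.
#' @param pixelSize mask resolution, micrometres per pixel (default 1.5).
#' @param regionFractions numeric(3): fraction of neurons in head,
#'   midbody and tail (default c(0.55, 0.15, 0.30), mirroring the dense
#'   head/tail ganglia and sparse midbody).
#' @param margin neurons are kept within this fraction of the local
#'   half-width (default 0.75).
#' @param targetExtent canonical x-extent for the ground truth (default
#'   c(0, 800) um).
#' @param seed integer seed.
#' @return list with \code{mask} ([HullMask-class]), \code{cloud} (raw
#'   frame), \code{truth} (canonical frame ground truth), and
#'   \code{spineLength}.
#' @export
synthWorm <- function(bodyLength = 1000, halfWidth = 40, taper = 0,
                      bendAngle = pi / 2, nNeurons = 300L, names = NULL,
                      pixelSize = 1.5,
                      regionFractions = c(0.55, 0.15, 0.30),
                      margin = 0.75, targetExtent = c(0, 800), seed = 0L) {
  if (missing(names)) names <- neuronNames()
  if (!is.null(names) && length(names) < nNeurons)
    stop("need at least nNeurons names")
  if (abs(bendAngle) > 1e-9 && bodyLength / abs(bendAngle) <= 2 * halfWidth)
    stop("bend radius must exceed the worm width (self-intersecting spine)")
  if (abs(bendAngle) >= 2 * pi)
    stop("bendAngle must be below a full turn (self-intersecting spine)")
  sp <- .spineFun(bodyLength, bendAngle)
  hOf <- function(a) halfWidth * (1 - taper * a / bodyLength)
  ## --- mask: union of discs of radius h(a) centered on the spine ---
  aGrid <- seq(0 + hOf(0), bodyLength - hOf(bodyLength), by = pixelSize / 2)
  ctr <- sp$pos(aGrid)
  rad <- hOf(aGrid)
  pad <- 4 * pixelSize
  x0 <- min(ctr[, 1] - rad) - pad; x1 <- max(ctr[, 1] + rad) + pad
  y0 <- min(ctr[, 2] - rad) - pad; y1 <- max(ctr[, 2] + rad) + pad
  nc <- ceiling((x1 - x0) / pixelSize)
  nr <- ceiling((y1 - y0) / pixelSize)
  grid <- matrix(FALSE, nr, nc)
  ## pixel (r, c) center: x = x0 + (c - 0.5) px, y = y0 + (r - 0.5) px
  for (i in seq_along(aGrid)) {
    r <- rad[i]
    clo <- max(1L, floor((ctr[i, 1] - r - x0) / pixelSize))
    chi <- min(nc, ceiling((ctr[i, 1] + r - x0) / pixelSize) + 1L)
    rlo <- max(1L, floor((ctr[i, 2] - r - y0) / pixelSize))
    rhi <- min(nr, ceiling((ctr[i, 2] + r - y0) / pixelSize) + 1L)
    if (clo > chi || rlo > rhi) next
    cx <- x0 + (clo:chi - 0.5) * pixelSize
    cy <- y0 + (rlo:rhi - 0.5) * pixelSize
    d2 <- outer((cy - ctr[i, 2])^2, (cx - ctr[i, 1])^2, "+")
    grid[rlo:rhi, clo:chi] <- grid[rlo:rhi, clo:chi] | (d2 <= r^2)
  }
  mask <- hullMask(grid, pixelSize)
  ## --- neurons: head/tail-dense arc-length distribution ---
  stopifnot(length(regionFractions) == 3L,
            abs(sum(regionFractions) - 1) < 1e-9)
  nHead <- round(nNeurons * regionFractions[1])
  nTail <- round(nNeurons * regionFractions[3])
  nMid <- nNeurons - nHead - nTail
  aLo <- hOf(0) * 1.2
  aHi <- bodyLength - hOf(bodyLength) * 1.2
  headEnd <- aLo + 0.15 * (aHi - aLo)
  tailStart <- aLo + 0.85 * (aHi - aLo)
  sim <- withr::with_seed(seed, {
    a <- c(stats::runif(nHead, aLo, headEnd),
           stats::runif(nMid, headEnd, tailStart),
           stats::runif(nTail, tailStart, aHi))
    u <- sqrt(stats::runif(nNeurons))
    phi <- stats::runif(nNeurons, 0, 2 * pi)
    list(a = a, u = u, phi = phi)
  })
  rOff <- sim$u * margin * hOf(sim$a)
  v <- rOff * cos(sim$phi)
  zz <- rOff * sin(sim$phi)
  xy <- sp$pos(sim$a) + sp$normal(sim$a) * v
  raw <- cbind(x = xy[, 1], y = xy[, 2], z = zz)
  ids <- if (is.null(names)) NULL else sort(names)[seq_len(nNeurons)]
  cloud <- pointCloud(raw - cbind(x0, y0, 0)[rep(1, nNeurons), ],
                      ids = ids, frameTag = "raw")
  ## ground truth in the canonical frame (exact for taper = 0)
  hHead <- hOf(0); hTail <- hOf(bodyLength)
  sc <- (targetExtent[2] - targetExtent[1]) / (bodyLength - hHead - hTail)
  truth <- pointCloud(cbind(x = (sim$a - hHead) * sc + targetExtent[1],
                            y = v * sc, z = zz * sc),
                      ids = ids, frameTag = "canonical")
  list(mask = mask, cloud = cloud, truth = truth,
       spineLength = bodyLength, scale = sc)
}
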