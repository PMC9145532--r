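#' @include pointcloud.R
NULL

.delimFor <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a neuron point cloud from delimited text
#'
#' Reads a CSV/TSV table (delimiter chosen by file extension) with one row
#' per neuron. Coordinate columns are interpreted as micrometres. The
#' \code{name} and \code{color} columns are optional; when the name column
#' is present its values must be non-empty and unique.
#'
#' @param path path to a readable delimited text file.
#' @param dialect named list mapping the logical fields \code{name},
#'   \code{x}, \code{y}, \code{z}, \code{color} to column names in the
#'   file. Defaults to the identity mapping.
#' @param frameTag frame annotation for the cloud ("raw" or "canonical").
#' @return a [NeuronPointCloud-class] preserving row order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("name,x,y,z", "AVAL,1,2,3", "AVAR,4,5,6"), f)
#' readPointCloud(f)
#' @export
readPointCloud <- function(path, dialect = list(), frameTag = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- utils::modifyList(
    list(name = "name", x = "x", y = "y", z = "z", color = "color"), dialect)
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"",
                          stringsAsFactors = FALSE)
  for (ax in c("x", "y", "z"))
    if (!map[[ax]] %in% names(df))
      stop("missing required coordinate column: ", map[[ax]])
  parseNum <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    bad <- c(bad, which(!nzchar(df[[col]])))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row(s) %s",
                   col, paste(sort(unique(bad)), collapse = ", ")))
    v
  }
  cc <- cbind(x = parseNum(map$x), y = parseNum(map$y), z = parseNum(map$z))
  ids <- NULL
  if (map$name %in% names(df)) {
    ids <- df[[map$name]]
    if (any(!nzchar(ids)))
      stop("empty neuron name at data row(s) ",
           paste(which(!nzchar(ids)), collapse = ", "))
    if (anyDuplicated(ids))
      stop("duplicate neuron names at data row(s) ",
           paste(which(duplicated(ids)), collapse = ", "))
  }
  colors <- NULL
  if (map$color %in% names(df)) {
    raw <- df[[map$color]]
    if (any(nzchar(raw))) {
      if (any(!nzchar(raw)))
        stop("color must be defined for every neuron or none")
      colors <- suppressWarnings(as.integer(raw))
      if (anyNA(colors))
        stop("non-integer color value at data row(s) ",
             paste(which(is.na(colors)), collapse = ", "))
    }
  }
  pointCloud(cc, ids = ids, colors = colors, frameTag = frameTag)
}

#' Write a neuron point cloud to delimited text
#'
#' Writes the cloud as CSV/TSV (delimiter by extension) with a header row.
#' Coordinates are written at full double precision (17 significant
#' digits) so that write-then-read is lossless.
#'
#' @param cloud a valid [NeuronPointCloud-class].
#' @param path output file path; extension selects the delimiter.
#' @return invisibly, \code{path}.
#' @export
writePointCloud <- function(cloud, path) {
  stopifnot(is(cloud, "NeuronPointCloud"))
  validObject(cloud)
  sep <- .delimFor(path)
  cols <- list()
  if (length(cloud@ids)) cols$name <- cloud@ids
  cols$x <- sprintf("%.17g", cloud@coords[, 1])
  cols$y <- sprintf("%.17g", cloud@coords[, 2])
  cols$z <- sprintf("%.17g", cloud@coords[, 3])
  if (length(cloud@colors)) cols$color <- as.character(cloud@colors)
  header <- paste(names(cols), collapse = sep)
  if (nNeurons(cloud) == 0L) {
    lines <- header
  } else {
    body <- do.call(paste, c(unname(cols), list(sep = sep)))
    lines <- c(header, body)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

## 4-connected component count via flood fill (iterative, label matrix)
.countComponents <- function(g) {
  lab <- matrix(0L, nrow(g), ncol(g))
  ncomp <- 0L
  nr <- nrow(g)
  idx <- which(g & lab == 0L)
  while (length(idx)) {
    ncomp <- ncomp + 1L
    stack <- idx[1]
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[cur] != 0L) next
      lab[cur] <- ncomp
      r <- (cur - 1L) %% nr + 1L
      nb <- c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
              cur - nr, cur + nr)
      nb <- nb[nb >= 1L & nb <= length(g)]
      nb <- nb[g[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
    idx <- which(g & lab == 0L)
  }
  attr(ncomp, "labels") <- lab
  ncomp
}

#' Read a binary worm hull mask from a raster image
#'
#' Reads a single-channel TIFF or PNG, binarizes it (values above half the
#' maximum are foreground unless already two-valued), keeps the largest
#' 4-connected foreground component (discarding smaller blobs with a
#' warning), and attaches the pixel size.
#'
#' @param path path to a TIFF (.tif/.tiff) or PNG (.png) image.
#' @param pixelSize micrometres per pixel (isotropic).
#' @return a [HullMask-class]. Errors if the foreground is empty or
#'   touches the image border (pad the image in that case).
#' @export
readHullMask <- function(path, pixelSize) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else stop("unsupported raster format (use TIFF or PNG): ", path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  hullMask(img > max(img, 0) / 2, pixelSize)
}

#' Construct a HullMask from a logical matrix
#'
#' @param grid logical (or numeric 0/1) matrix; TRUE = worm interior.
#' @param pixelSize micrometres per pixel.
#' @return a [HullMask-class]
#' @export
hullMask <- function(grid, pixelSize) {
  grid <- as.matrix(grid)
  if (!is.logical(grid)) grid <- grid > 0
  if (!any(grid)) stop("mask has empty foreground")
  ncomp <- .countComponents(grid)
  if (ncomp > 1L) {
    lab <- attr(ncomp, "labels")
    keep <- which.max(tabulate(lab[lab > 0L]))
    grid <- lab == keep
    warning(sprintf("mask had %d foreground components; kept the largest",
                    as.integer(ncomp)))
  }
  if (any(grid[1, ]) || any(grid[nrow(grid), ]) ||
      any(grid[, 1]) || any(grid[, ncol(grid)]))
    stop("foreground touches the raster border; pad the image first")
  new("HullMask", grid = grid, pixelSize = as.numeric(pixelSize))
}

#' Read / write an atlas table
#'
#' Atlas files use the point-cloud CSV/TSV dialect with mandatory
#' \code{name} column, optional \code{color}, optional per-axis spread
#' columns \code{sx,sy,sz}, and optional contributing-worm \code{count}.
#'
#' @param path file path.
#' @return \code{readAtlas}: an [Atlas-class].
#' @export
readAtlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("name", "x", "y", "z"))
    if (!col %in% names(df)) stop("atlas file missing column: ", col)
  pos <- as.matrix(df[, c("x", "y", "z")])
  colnames(pos) <- c("x", "y", "z")
  spread <- if (all(c("sx", "sy", "sz") %in% names(df)))
    as.matrix(df[, c("sx", "sy", "sz")])
  else matrix(numeric(0), 0, 3)
  new("Atlas",
      positions = pos,
      ids = as.character(df$name),
      spread = spread,
      colors = if ("color" %in% names(df)) as.integer(df$color)
               else integer(0),
      counts = if ("count" %in% names(df)) as.integer(df$count)
               else rep(1L, nrow(df)),
      extent = range(pos[, 1]))
}

#' @rdname readAtlas
#' @param atlas an [Atlas-class]
#' @return \code{writeAtlas}: invisibly, \code{path}.
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "Atlas"))
  df <- data.frame(name = atlas@ids,
                   x = atlas@positions[, 1],
                   y = atlas@positions[, 2],
                   z = atlas@positions[, 3],
                   stringsAsFactors = FALSE)
  if (nrow(atlas@spread)) {
    df$sx <- atlas@spread[, 1]; df$sy <- atlas@spread[, 2]
    df$sz <- atlas@spread[, 3]
  }
  if (length(atlas@colors)) df$color <- atlas@colors
  df$count <- atlas@counts
  utils::write.table(df, path, sep = .delimFor(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname Atlas-class
#' @param x an [Atlas-class]
#' @param ... ignored
#' @export
setMethod("asPointCloud", "Atlas", function(x, ...) {
  pointCloud(x@positions, ids = x@ids,
             colors = if (length(x@colors)) x@colors else NULL,
             frameTag = "canonical")
})
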