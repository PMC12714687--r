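#' 3D topology-preserving skeletonization (curve thinning)
#'
#' Thins a binary mask to a one-voxel-wide centerline by iteratively
#' deleting simple border points in six directional sub-iterations
#' (up, down, north, south, east, west; fixed order, sequential deletion
#' with recheck). A point is deleted only if removal preserves topology
#' (Bertrand-Malandain simple-point characterization: one 26-connected
#' foreground component in the punctured neighborhood and one 6-connected
#' background component in the 18-neighborhood touching a face neighbor)
#' and it is not a curve endpoint (fewer than two foreground 26-neighbors).
#' The result is a subset of the foreground, preserves the number of
#' 26-connected components, and the operation is idempotent.
#'
#' @param mask a \linkS4class{LabelMap}/\linkS4class{VoxelGrid} or 3D array;
#'   foreground = nonzero.
#' @return A logical 3D array marking skeleton voxels.
#' @export
skeletonize3d <- function(mask) {
  m <- if (is(mask, "VoxelGrid")) mask@values > 0 else mask > 0
  stopifnot(length(dim(m)) == 3L)
  if (!any(m)) return(array(FALSE, dim(m)))
  array(cpp_skeletonize(as.logical(m), dim(m)), dim(m))
}

# bounding box (with 1-voxel pad) of a logical array; NULL when empty
.bbox <- function(m) {
  w <- which(m, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, dim(m))
  list(lo = lo, hi = hi)
}

#' Per-label centerline extraction
#'
#' Applies \code{\link{skeletonize3d}} to each label of a
#' \linkS4class{LabelMap} independently (each label as its own binary mask).
#' Labels listed in the vocabulary but absent from the map yield empty
#' entries.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param labels integer label codes to process (default: whole vocabulary).
#' @return A \linkS4class{CenterlineSet}.
#' @export
labelCenterlines <- function(labelmap, labels = NULL) {
  stopifnot(is(labelmap, "LabelMap"))
  v <- labelmap@values
  if (is.null(labels)) labels <- as.integer(names(labelmap@vocabulary))
  pts <- lapply(labels, function(lab) {
    m <- v == lab
    bb <- .bbox(m)
    if (is.null(bb))
      return(matrix(integer(), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
    sub <- m[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
             drop = FALSE]
    sk <- skeletonize3d(sub)
    w <- which(sk, arr.ind = TRUE)
    w <- w + matrix(bb$lo - 1L, nrow(w), 3, byrow = TRUE)
    colnames(w) <- c("i", "j", "k")
    w
  })
  names(pts) <- as.character(labels)
  new("CenterlineSet", points = pts, dim = dim(v), spacing = labelmap@spacing)
}

.off26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Are two labels voxel-adjacent?
#'
#' TRUE iff some voxel of label \code{a} has a 26-neighbor carrying label
#' \code{b} (or \code{a == b} with at least one voxel present). This is the
#' strict voxel-connectivity check used for the PCom inclusion rule: a
#' single-voxel gap between two labels breaks adjacency.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param a,b label codes (integer) or artery names from the vocabulary.
#' @return logical(1). Symmetric in \code{a} and \code{b}.
#' @export
labelsAdjacent <- function(labelmap, a, b) {
  stopifnot(is(labelmap, "LabelMap"))
  a <- .resolveLabel(labelmap, a)
  b <- .resolveLabel(labelmap, b)
  v <- labelmap@values
  ma <- v == a
  if (a == b) return(any(ma))
  mb <- v == b
  ba <- .bbox(ma)
  bb <- .bbox(mb)
  if (is.null(ba) || is.null(bb)) return(FALSE)
  lo <- pmax(pmin(ba$lo, bb$lo), 1L)
  hi <- pmax(ba$hi, bb$hi)
  ma <- ma[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mb <- mb[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(ma)
  for (r in seq_len(nrow(.off26))) {
    o <- .off26[r, ]
    ia <- lapply(1:3, function(k) max(1, 1 + o[k]):min(d[k], d[k] + o[k]))
    ib <- lapply(1:3, function(k) max(1, 1 - o[k]):min(d[k], d[k] - o[k]))
    if (any(ma[ia[[1]], ia[[2]], ia[[3]]] & mb[ib[[1]], ib[[2]], ib[[3]]]))
      return(TRUE)
  }
  FALSE
}

.resolveLabel <- function(labelmap, x) {
  if (is.character(x)) {
    hit <- names(labelmap@vocabulary)[labelmap@vocabulary == x]
    if (!length(hit)) stop("unknown artery name: ", x)
    return(as.integer(hit[1]))
  }
  x <- as.integer(x)
  if (!as.character(x) %in% names(labelmap@vocabulary))
    stop("label code not in vocabulary: ", x)
  x
}
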