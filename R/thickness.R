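#' @useDynLib cowmeter, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# normalize a mask argument: LabelMap/VoxelGrid (foreground = values > 0)
# or logical/numeric array with an explicit spacing
.asMask <- function(mask, spacing = NULL) {
  if (is(mask, "VoxelGrid")) {
    list(m = mask@values > 0, spacing = mask@spacing,
         orientation = mask@orientation, origin = mask@origin)
  } else {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L, all(spacing > 0))
    list(m = mask > 0, spacing = as.numeric(spacing),
         orientation = "RAS", origin = c(0, 0, 0))
  }
}

# squared Euclidean distance map (mm^2) to the nearest background voxel
# center; Inf on foreground when the mask has no background at all
.edt2 <- function(m, spacing) {
  d2 <- cpp_edt_sq(as.logical(m), dim(m), spacing)
  d2[d2 >= 1e29] <- Inf
  array(d2, dim(m))
}

#' Euclidean distance map of a binary mask
#'
#' Each foreground voxel receives the spacing-aware Euclidean distance (mm)
#' from its center to the nearest background voxel center; background voxels
#' hold 0. An empty foreground yields an all-zero map. Foreground voxels of
#' a mask with no background at all receive \code{Inf}.
#'
#' @param mask a \linkS4class{LabelMap}/\linkS4class{VoxelGrid} (foreground =
#'   nonzero) or a 3D logical/numeric array.
#' @param spacing numeric(3) voxel spacing in mm; ignored when \code{mask}
#'   carries its own geometry.
#' @return A \linkS4class{VoxelGrid} of distances in mm.
#' @export
distanceMap <- function(mask, spacing = NULL) {
  a <- .asMask(mask, spacing)
  d <- sqrt(.edt2(a$m, a$spacing))
  voxelGrid(d, spacing = a$spacing, orientation = a$orientation,
            origin = a$origin)
}

#' Local thickness (largest inscribed sphere diameter) of a binary mask
#'
#' For every foreground voxel p, the local thickness is
#' \deqn{LT(p) = \max \{ 2 d(c) : c \in FG,\; \|p - c\| \le d(c) \}}
#' where d is the distance map and distances are spacing-aware
#' center-to-center distances. Thus LT(p) is the diameter of the largest
#' sphere that fits inside the structure and contains p, and
#' LT(p) >= 2 d(p) everywhere on the foreground. Computed by
#' distance-ordered sphere painting, which is exactly equivalent to the
#' exhaustive definition (see \code{\link{localThicknessOracle}}).
#'
#' @inheritParams distanceMap
#' @return A \linkS4class{ThicknessMap} (mm; zero on background).
#' @export
localThickness <- function(mask, spacing = NULL) {
  a <- .asMask(mask, spacing)
  d2 <- .edt2(a$m, a$spacing)
  if (any(is.infinite(d2)))
    stop("mask has no background voxels; thickness is unbounded")
  lt <- cpp_local_thickness(as.vector(d2), dim(a$m), a$spacing)
  new("ThicknessMap", values = array(lt, dim(a$m)), spacing = a$spacing,
      orientation = a$orientation, origin = a$origin)
}

#' Brute-force local thickness (test oracle)
#'
#' Same contract as \code{\link{localThickness}}, evaluated by exhaustive
#' iteration over every candidate sphere center. Intended for small masks
#' (<= ~16^3); complexity is O(#foreground x #voxels in sphere bbox).
#'
#' @inheritParams distanceMap
#' @return A \linkS4class{ThicknessMap}.
#' @export
localThicknessOracle <- function(mask, spacing = NULL) {
  a <- .asMask(mask, spacing)
  m <- a$m
  sp <- a$spacing
  d2 <- .edt2(m, sp)
  if (any(is.infinite(d2)))
    stop("mask has no background voxels; thickness is unbounded")
  dm <- dim(m)
  out <- array(0, dm)
  fg <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    c0 <- fg[r, ]
    r2 <- d2[c0[1], c0[2], c0[3]]
    val <- 2 * sqrt(r2)
    for (k in seq_len(dm[3])) {
      tz <- ((k - c0[3]) * sp[3])^2
      for (j in seq_len(dm[2])) {
        ty <- ((j - c0[2]) * sp[2])^2
        for (i in seq_len(dm[1])) {
          tx <- ((i - c0[1]) * sp[1])^2
          if (((tx + ty) + tz) <= r2 && m[i, j, k] && out[i, j, k] < val)
            out[i, j, k] <- val
        }
      }
    }
  }
  new("ThicknessMap", values = out, spacing = sp,
      orientation = a$orientation, origin = a$origin)
}
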