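#' @import methods
NULL

#' VoxelGrid: a 3D scalar lattice with physical geometry
#'
#' Base container for volumetric data. Voxel centers sit at
#' \code{origin + (i - 0.5) * spacing} along each axis (1-based index
#' \code{i}), so \code{origin} is the world coordinate of the minimal corner
#' of the volume's bounding box, expressed in anatomical RAS millimeters.
#' \code{orientation} gives the anatomical direction of each storage axis
#' using the usual three-letter codes (canonical form \code{"RAS"}).
#'
#' @slot values 3D array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm (positive).
#' @slot orientation character(1), e.g. \code{"RAS"}, \code{"LPS"}.
#' @slot origin numeric(3), mm, minimal corner of the volume box (RAS frame).
#' @export
setClass("VoxelGrid",
  representation(
    values = "array",
    spacing = "numeric",
    orientation = "character",
    origin = "numeric"
  ),
  prototype(
    spacing = c(1, 1, 1),
    orientation = "RAS",
    origin = c(0, 0, 0)
  )
)

.validOrientation <- function(o) {
  if (length(o) != 1L || is.na(o) || nchar(o) != 3L) return(FALSE)
  ch <- strsplit(o, "")[[1]]
  axis <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)[ch]
  !anyNA(axis) && !anyDuplicated(axis)
}

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (!.validOrientation(object@orientation))
    msg <- c(msg, "orientation must be a valid 3-letter axis code (e.g. 'RAS')")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' LabelMap: an integer-labeled segmentation volume
#'
#' A \linkS4class{VoxelGrid} holding non-negative integer artery labels
#' (0 = background) together with a vocabulary mapping label codes to
#' artery names.
#'
#' @slot vocabulary named character vector; names are label codes (as
#'   character), values are artery names such as \code{"ICA-L"}.
#' @export
setClass("LabelMap",
  contains = "VoxelGrid",
  representation(vocabulary = "character")
)

setValidity("LabelMap", function(object) {
  msg <- character()
  v <- object@values
  if (!(is.integer(v) || (is.numeric(v) && all(v == round(v)))))
    msg <- c(msg, "label values must be integers")
  if (any(v < 0)) msg <- c(msg, "label values must be non-negative")
  voc <- object@vocabulary
  if (length(voc) && is.null(names(voc)))
    msg <- c(msg, "vocabulary must be named by label code")
  present <- setdiff(unique(as.vector(v)), 0)
  known <- suppressWarnings(as.integer(names(voc)))
  if (length(present) && !all(present %in% known))
    msg <- c(msg, sprintf("labels absent from vocabulary: %s",
                          paste(setdiff(present, known), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ThicknessMap: per-voxel local diameter in mm
#'
#' A \linkS4class{VoxelGrid} of non-negative local-thickness values
#' (diameter of the largest inscribed sphere containing each voxel);
#' zero on background.
#' @export
setClass("ThicknessMap", contains = "VoxelGrid")

setValidity("ThicknessMap", function(object) {
  if (any(object@values < 0)) "thickness values must be non-negative" else TRUE
})

#' CenterlineSet: per-label skeleton voxel coordinates
#'
#' @slot points named list (by label code, as character) of integer matrices
#'   with one row per skeleton voxel and columns (i, j, k), 1-based indices
#'   into the parent grid.
#' @slot dim integer(3), parent grid dimensions.
#' @slot spacing numeric(3), parent grid spacing (mm).
#' @export
setClass("CenterlineSet",
  representation(points = "list", dim = "integer", spacing = "numeric")
)

setValidity("CenterlineSet", function(object) {
  msg <- character()
  if (length(object@dim) != 3L) msg <- c(msg, "dim must have length 3")
  for (m in object@points) {
    if (!is.matrix(m) || ncol(m) != 3L)
      msg <- c(msg, "each centerline must be an n x 3 index matrix")
    else if (nrow(m) && (any(m < 1) || any(m > rep(object@dim, each = nrow(m)))))
      msg <- c(msg, "centerline indices out of grid bounds")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' TubeSpec: one tube of a digital vascular phantom
#'
#' @slot label integer label code painted for this tube.
#' @slot points numeric matrix (n x 3) of centerline polyline vertices in
#'   world mm coordinates.
#' @slot diameter numeric(1), tube diameter in mm (constant along the tube).
#' @export
setClass("TubeSpec",
  representation(label = "integer", points = "matrix", diameter = "numeric")
)

setValidity("TubeSpec", function(object) {
  msg <- character()
  if (object@diameter <= 0) msg <- c(msg, "diameter must be positive")
  if (!is.numeric(object@points) || ncol(object@points) != 3L ||
      nrow(object@points) < 1L)
    msg <- c(msg, "points must be an n x 3 numeric matrix")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: a parametric multi-tube phantom
#'
#' @slot tubes list of \linkS4class{TubeSpec}.
#' @slot fov numeric 2 x 3 matrix, rows (lo, hi): field of view box in mm.
#' @slot voxel numeric(1), isotropic voxel size in mm.
#' @slot vocabulary named character vector, label code -> artery name.
#' @slot priority integer vector of label codes; earlier codes win at
#'   overlaps (trunks dominate at junctions).
#' @slot pv_frac numeric(1) in [0, 1): segmentation partial-volume emulation.
#'   A voxel is included when its center lies within \code{pv_frac * voxel}
#'   of the tube surface (0 = pure center-in rasterization; 0.5 emulates a
#'   bright-blood segmentation that includes any voxel touching the vessel).
#' @export
setClass("PhantomSpec",
  representation(tubes = "list", fov = "matrix", voxel = "numeric",
                 vocabulary = "character", priority = "integer",
                 pv_frac = "numeric"),
  prototype(pv_frac = 0)
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!all(dim(object@fov) == c(2, 3)) || any(object@fov[1, ] >= object@fov[2, ]))
    msg <- c(msg, "fov must be a 2 x 3 (lo, hi) matrix with lo < hi")
  if (length(object@voxel) != 1L || object@voxel <= 0)
    msg <- c(msg, "voxel must be a single positive size (mm)")
  if (!all(vapply(object@tubes, is, TRUE, "TubeSpec")))
    msg <- c(msg, "tubes must all be TubeSpec objects")
  if (length(object@pv_frac) != 1L || object@pv_frac < 0 || object@pv_frac >= 1)
    msg <- c(msg, "pv_frac must be a single value in [0, 1)")
  if (length(msg)) msg else TRUE
})
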