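#' Construct a VoxelGrid
#'
#' @param values 3D array.
#' @param spacing numeric(3), mm per axis.
#' @param orientation 3-letter axis code (default "RAS").
#' @param origin numeric(3), mm, minimal corner of the volume box.
#' @return A \linkS4class{VoxelGrid}.
#' @export
voxelGrid <- function(values, spacing = c(1, 1, 1), orientation = "RAS",
                      origin = c(0, 0, 0)) {
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      orientation = orientation, origin = as.numeric(origin))
}

#' Construct a LabelMap
#'
#' @inheritParams voxelGrid
#' @param vocabulary named character vector mapping label codes (names) to
#'   artery names; defaults to names auto-generated from the labels present.
#' @return A \linkS4class{LabelMap}.
#' @export
labelMap <- function(values, spacing = c(1, 1, 1), orientation = "RAS",
                     origin = c(0, 0, 0), vocabulary = NULL) {
  storage.mode(values) <- "integer"
  if (is.null(vocabulary)) {
    present <- setdiff(sort(unique(as.vector(values))), 0L)
    vocabulary <- stats::setNames(paste0("label-", present),
                                  as.character(present))
  }
  new("LabelMap", values = values, spacing = as.numeric(spacing),
      orientation = orientation, origin = as.numeric(origin),
      vocabulary = vocabulary)
}

#' Default Circle-of-Willis label vocabulary
#'
#' Codes for the arteries measured bilaterally (ICA, ACA A1, MCA M1, PCom,
#' PCA P1) plus the basilar artery, with optional PCA P2 segments and the
#' anterior communicating artery as extra codes.
#' @return Named character vector, label code -> artery name.
#' @export
cwLabelVocabulary <- function() {
  c(`1` = "ICA-L", `2` = "ICA-R", `3` = "BA",
    `4` = "ACA-A1-L", `5` = "ACA-A1-R",
    `6` = "MCA-M1-L", `7` = "MCA-M1-R",
    `8` = "PCom-L", `9` = "PCom-R",
    `10` = "PCA-P1-L", `11` = "PCA-P1-R",
    `12` = "PCA-P2-L", `13` = "PCA-P2-R",
    `14` = "ACom")
}

.sidecarPath <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
}

.codeToAxis <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
.codeToSign <- c(R = 1, L = -1, A = 1, P = -1, S = 1, I = -1)

# full 4x4 affine (index0 -> voxel-center world mm) for a grid in its own
# storage orientation
.gridAffine <- function(dims, spacing, orientation, origin) {
  ch <- strsplit(orientation, "")[[1]]
  ax <- .codeToAxis[ch]
  sg <- .codeToSign[ch]
  A <- matrix(0, 4, 4)
  A[4, 4] <- 1
  for (j in 1:3) {
    A[ax[j], j] <- sg[j] * spacing[j]
    extent <- spacing[j] * dims[j]
    A[ax[j], 4] <- if (sg[j] > 0) origin[ax[j]] + 0.5 * spacing[j]
                   else origin[ax[j]] + extent - 0.5 * spacing[j]
  }
  A
}

#' Read a labeled NIfTI segmentation
#'
#' Voxel values must be integers (a format error is raised otherwise) and
#' the header must carry positive voxel spacings. The label vocabulary is
#' taken from \code{vocabulary}, from a sidecar JSON file
#' (\code{<image>.labels.json}, an object mapping code to name) when one
#' exists, or auto-generated.
#'
#' @param path a NIfTI-1 file (.nii or .nii.gz).
#' @param vocabulary optional named character vector, code -> name.
#' @return A \linkS4class{LabelMap}.
#' @export
readLabelMap <- function(path, vocabulary = NULL) {
  img <- RNifti::readNifti(path)
  v <- array(as.vector(img), dim(img))  # plain array, no image attributes
  if (length(dim(v)) == 4L && dim(v)[4] == 1L) dim(v) <- dim(v)[1:3]
  if (length(dim(v)) != 3L)
    stop("expected a 3D volume, got dimensions ",
         paste(dim(v), collapse = " x "))
  if (any(!is.finite(v)) || any(v != round(v)))
    stop("format error: voxel values are not integers")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("format error: missing or non-positive voxel spacing in header")
  orient <- RNifti::orientation(RNifti::xform(img))
  A <- unclass(RNifti::xform(img))
  corners <- as.matrix(expand.grid(c(-0.5, dim(v)[1] - 0.5),
                                   c(-0.5, dim(v)[2] - 0.5),
                                   c(-0.5, dim(v)[3] - 0.5)))
  world <- t(A[1:3, 1:3] %*% t(corners)) +
    matrix(A[1:3, 4], nrow(corners), 3, byrow = TRUE)
  origin <- apply(world, 2, min)
  if (is.null(vocabulary)) {
    sc <- .sidecarPath(path)
    if (file.exists(sc)) {
      voc <- jsonlite::read_json(sc, simplifyVector = TRUE)
      vocabulary <- stats::setNames(as.character(voc), names(voc))
    }
  }
  labelMap(v, spacing = sp, orientation = orient, origin = origin,
           vocabulary = vocabulary)
}

#' Write a LabelMap to NIfTI (+ vocabulary sidecar JSON)
#'
#' @param x a \linkS4class{LabelMap}.
#' @param path output .nii or .nii.gz path; the vocabulary is written next
#'   to it as \code{<image>.labels.json}.
#' @return \code{path}, invisibly.
#' @export
writeLabelMap <- function(x, path) {
  stopifnot(is(x, "LabelMap"))
  A <- .gridAffine(dim(x@values), x@spacing, x@orientation, x@origin)
  attr(A, "code") <- 2L
  img <- RNifti::asNifti(structure(x@values, pixdim = x@spacing))
  RNifti::qform(img) <- A
  RNifti::sform(img) <- A
  RNifti::writeNifti(img, path, datatype = "int32")
  jsonlite::write_json(as.list(x@vocabulary), .sidecarPath(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Reorient a grid to canonical RAS axis order
#'
#' Pure axis permutation and flipping; no interpolation. The voxel-value
#' multiset is preserved exactly and spacing is permuted consistently.
#' Applying the operation twice equals applying it once.
#'
#' @param grid a \linkS4class{VoxelGrid} (or subclass).
#' @return The same class of object, in RAS orientation.
#' @export
reorientRAS <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  o <- grid@orientation
  if (!.validOrientation(o)) stop("ambiguous orientation metadata: ", o)
  if (o == "RAS") return(grid)
  ch <- strsplit(o, "")[[1]]
  ax <- .codeToAxis[ch]
  sg <- .codeToSign[ch]
  v <- grid@values
  idx <- lapply(1:3, function(j) if (sg[j] < 0) rev(seq_len(dim(v)[j]))
                                 else seq_len(dim(v)[j]))
  v <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  perm <- order(ax)  # perm[a] = storage axis that carries anatomical axis a
  v <- aperm(v, perm)
  out <- grid
  out@values <- v
  out@spacing <- grid@spacing[perm]
  out@orientation <- "RAS"
  validObject(out)
  out
}

#' Resample a LabelMap to an isotropic grid by nearest neighbor
#'
#' The output grid shares the input's world origin and covers the input
#' bounding box; each output voxel takes the label of the nearest input
#' voxel center (ties broken toward the lower input index). No label absent
#' from the input can appear in the output.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param iso_mm target isotropic voxel size in mm (positive).
#' @return A resampled \linkS4class{LabelMap}.
#' @export
resampleNearest <- function(labelmap, iso_mm) {
  stopifnot(is(labelmap, "LabelMap"), iso_mm > 0)
  s <- labelmap@spacing
  n <- dim(labelmap@values)
  m <- pmax(1L, as.integer(ceiling(n * s / iso_mm - 1e-9)))
  # nearest input center to output center x = (i - 0.5) * iso: j = ceiling(x/s)
  ix <- lapply(1:3, function(a) {
    x <- (seq_len(m[a]) - 0.5) * iso_mm
    pmin(pmax(ceiling(x / s[a]), 1L), n[a])
  })
  v <- labelmap@values[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  labelMap(v, spacing = rep(iso_mm, 3), orientation = labelmap@orientation,
           origin = labelmap@origin, vocabulary = labelmap@vocabulary)
}

# ---------------------------------------------------------------------------
# measurement tables
# ---------------------------------------------------------------------------

.mtCols <- c("participant_id", "artery", "side", "diameter_mm", "source")

#' Construct / validate a measurement table
#'
#' Rows of (participant_id, artery, side, diameter_mm, source). Missing
#' diameters are \code{NA}; side is \code{"L"}, \code{"R"} or \code{NA}
#' (unpaired arteries); source is \code{"manual"} or \code{"auto"}. The key
#' (participant_id, artery, side, source) must be unique and present
#' diameters must be positive.
#'
#' @param df data.frame with the columns above.
#' @return The validated data.frame (class \code{data.frame}).
#' @export
measurementTable <- function(df) {
  if (!all(.mtCols %in% names(df)))
    stop("measurement table must have columns: ", paste(.mtCols, collapse = ", "))
  df <- df[, .mtCols]
  df$participant_id <- as.character(df$participant_id)
  df$artery <- as.character(df$artery)
  df$side <- as.character(df$side)
  df$side[!is.na(df$side) & df$side == ""] <- NA_character_
  df$diameter_mm <- as.numeric(df$diameter_mm)
  df$source <- as.character(df$source)
  if (!all(df$source %in% c("manual", "auto")))
    stop("source must be 'manual' or 'auto'")
  if (!all(is.na(df$side) | df$side %in% c("L", "R")))
    stop("side must be 'L', 'R' or NA")
  key <- paste(df$participant_id, df$artery,
               ifelse(is.na(df$side), "", df$side), df$source, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant, artery, side, source) keys")
  if (any(!is.na(df$diameter_mm) & df$diameter_mm <= 0))
    stop("present diameters must be positive")
  rownames(df) <- NULL
  df
}

#' Read a measurement CSV
#'
#' Header \code{participant_id,artery,side,diameter_mm,source}; empty
#' diameter fields encode missing measurements.
#' @param path CSV file path.
#' @return A validated measurement table.
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  df$diameter_mm <- suppressWarnings(as.numeric(df$diameter_mm))
  measurementTable(df)
}

#' Write a measurement CSV
#'
#' @param table a measurement table (see \code{\link{measurementTable}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMeasurements <- function(table, path) {
  df <- measurementTable(table)
  df$side[is.na(df$side)] <- ""
  df$diameter_mm <- ifelse(is.na(df$diameter_mm), "",
                           format(df$diameter_mm, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
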