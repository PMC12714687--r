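#' Arteries measured by the pipeline
#'
#' The bilaterally measured segments (ICA, ACA A1, MCA M1, PCom, PCA P1)
#' plus the basilar artery, 11 measurements in total. The anterior
#' communicating artery is not measured.
#'
#' @return data.frame with columns \code{artery} and \code{side}
#'   (\code{NA} side for the BA).
#' @export
cwMeasuredArteries <- function() {
  data.frame(
    artery = c(rep(c("ICA", "ACA-A1", "MCA-M1", "PCom", "PCA-P1"), each = 2),
               "BA"),
    side = c(rep(c("L", "R"), 5), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' The five isotropic study voxel sizes (mm)
#' @return numeric vector of voxel edge lengths.
#' @export
cwResolutions <- function() c(0.2083, 0.3125, 0.4, 0.5, 0.625)

.arteryLabelName <- function(artery, side) {
  if (is.na(side)) artery else paste(artery, side, sep = "-")
}

.FLAGS <- c("TOO_THIN", "PCOM_DISCONNECTED", "ABSENT")

#' Single-artery diameter from thickness along the centerline
#'
#' The artery diameter is the arithmetic mean of local-thickness values at
#' the label's centerline voxels. A label with no voxels yields a missing
#' diameter with the \code{ABSENT} flag. When the median centerline
#' thickness is below twice the voxel size the \code{TOO_THIN} flag is set
#' (the measurement needs at least two voxels across the lumen to be
#' reliable); the boundary is included because a median inscribed sphere of
#' two voxels across cannot resolve sub-voxel vessel width. The diameter is
#' still reported.
#'
#' @param labelmap the \linkS4class{LabelMap} the inputs were computed from.
#' @param label label code (integer) or artery name.
#' @param thickness \linkS4class{ThicknessMap} of the binary union mask at
#'   the same resolution.
#' @param centerlines \linkS4class{CenterlineSet} at the same resolution.
#' @return One-row data.frame: \code{label}, \code{diameter_mm},
#'   \code{n_centerline_voxels}, \code{flags} (";"-separated).
#' @export
arteryDiameter <- function(labelmap, label, thickness, centerlines) {
  stopifnot(is(labelmap, "LabelMap"), is(thickness, "ThicknessMap"),
            is(centerlines, "CenterlineSet"))
  if (!identical(dim(labelmap@values), dim(thickness@values)) ||
      !identical(dim(labelmap@values), centerlines@dim) ||
      max(abs(labelmap@spacing - thickness@spacing)) > 1e-9 ||
      max(abs(labelmap@spacing - centerlines@spacing)) > 1e-9)
    stop("resolution mismatch between labelmap, thickness and centerlines")
  code <- .resolveLabel(labelmap, label)
  pts <- centerlines@points[[as.character(code)]]
  if (is.null(pts))
    stop("no centerline entry for label ", code)
  if (nrow(pts) == 0L || !any(labelmap@values == code))
    return(data.frame(label = code, diameter_mm = NA_real_,
                      n_centerline_voxels = 0L, flags = "ABSENT",
                      stringsAsFactors = FALSE))
  lt <- thickness@values[pts]
  h <- max(labelmap@spacing)
  flags <- character()
  if (stats::median(lt) <= 2 * h) flags <- c(flags, "TOO_THIN")
  data.frame(label = code, diameter_mm = mean(lt),
             n_centerline_voxels = nrow(pts),
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Apply the PCom connectivity inclusion rule
#'
#' A posterior communicating artery is only a valid measurement when it is
#' voxel-connected (26-adjacency) to both the same-side ICA and the
#' same-side PCA (P1, or P2 when a P2 code exists in the vocabulary). A
#' PCom failing the rule -- even by a single disconnected voxel -- has its
#' diameter set to missing with the \code{PCOM_DISCONNECTED} flag. Absent
#' PComs are left untouched.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param results the per-artery result table from
#'   \code{\link{measureArteries}}.
#' @return The result table with the rule applied.
#' @export
applyPcomRule <- function(labelmap, results) {
  voc <- labelmap@vocabulary
  for (side in c("L", "R")) {
    i <- which(results$artery == "PCom" & results$side == side)
    if (!length(i)) next
    if (grepl("ABSENT", results$flags[i])) next
    pcom <- paste0("PCom-", side)
    ica <- paste0("ICA-", side)
    p1 <- paste0("PCA-P1-", side)
    p2 <- paste0("PCA-P2-", side)
    ok_ica <- ica %in% voc && labelsAdjacent(labelmap, pcom, ica)
    ok_pca <- (p1 %in% voc && labelsAdjacent(labelmap, pcom, p1)) ||
              (p2 %in% voc && labelsAdjacent(labelmap, pcom, p2))
    if (!(ok_ica && ok_pca)) {
      results$diameter_mm[i] <- NA_real_
      results$flags[i] <- paste(c(setdiff(strsplit(results$flags[i], ";")[[1]],
                                          ""), "PCOM_DISCONNECTED"),
                                collapse = ";")
    }
  }
  results
}

#' Measure all arteries of a labeled segmentation
#'
#' Full measurement pass: local thickness of the binary union of all labels,
#' per-label centerlines, mean thickness along each measured artery's
#' centerline, then the PCom connectivity rule.
#'
#' @param labelmap a \linkS4class{LabelMap} (isotropic resolution expected;
#'   resample first for anisotropic inputs).
#' @return data.frame with one row per measured artery: \code{artery},
#'   \code{side}, \code{diameter_mm}, \code{n_centerline_voxels},
#'   \code{flags}.
#' @export
measureArteries <- function(labelmap) {
  stopifnot(is(labelmap, "LabelMap"))
  arts <- cwMeasuredArteries()
  voc <- labelmap@vocabulary
  lt <- localThickness(labelmap)
  want <- vapply(seq_len(nrow(arts)),
                 function(r) .arteryLabelName(arts$artery[r], arts$side[r]), "")
  codes <- suppressWarnings(
    vapply(want, function(nm) {
      hit <- names(voc)[voc == nm]
      if (length(hit)) as.integer(hit[1]) else NA_integer_
    }, 0L))
  cls <- labelCenterlines(labelmap, labels = codes[!is.na(codes)])
  out <- do.call(rbind, lapply(seq_len(nrow(arts)), function(r) {
    if (is.na(codes[r]))
      return(data.frame(label = NA_integer_, diameter_mm = NA_real_,
                        n_centerline_voxels = 0L, flags = "ABSENT",
                        stringsAsFactors = FALSE))
    arteryDiameter(labelmap, codes[r], lt, cls)
  }))
  out <- cbind(arts, out)
  applyPcomRule(labelmap, out)
}

#' Measure all arteries and emit a measurement table
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param participant_id participant identifier for the emitted rows.
#' @return A measurement table (source \code{"auto"}); per-artery flags are
#'   attached as attribute \code{"details"}.
#' @export
measureAll <- function(labelmap, participant_id = "phantom") {
  res <- measureArteries(labelmap)
  tab <- measurementTable(data.frame(
    participant_id = participant_id,
    artery = res$artery, side = res$side,
    diameter_mm = res$diameter_mm, source = "auto",
    stringsAsFactors = FALSE))
  attr(tab, "details") <- res
  tab
}

#' Multi-resolution measurement study
#'
#' Resamples the label map to each isotropic voxel size by nearest neighbor
#' and runs the full measurement pass at each size.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param sizes positive voxel sizes in mm (default the five study sizes).
#' @param participant_id identifier for the emitted rows.
#' @return Named list (by voxel size) of measurement tables.
#' @export
resolutionStudy <- function(labelmap, sizes = cwResolutions(),
                            participant_id = "phantom") {
  stopifnot(length(sizes) >= 1, all(sizes > 0))
  out <- lapply(sizes, function(h)
    measureAll(resampleNearest(labelmap, h), participant_id))
  names(out) <- format(sizes, trim = TRUE)
  out
}

#' Phantom-ensemble voxel-size sensitivity study
#'
#' Generates an ensemble of Circle-of-Willis phantoms with jittered
#' diameters and, for each phantom and each voxel size, rasterizes the
#' phantom's segmentation at that size (the segmentation, like one derived
#' from an image resampled to that resolution, is resolution-dependent:
#' partial-volume inclusion scales with the voxel) and runs the full
#' measurement pass. This is the experiment behind the voxel-size bias
#' trend: estimated diameters grow with voxel size while the ground truth
#' stays fixed.
#'
#' @param n_phantoms ensemble size (default 20).
#' @param sizes voxel sizes in mm (default the five study sizes).
#' @param seed integer seed; phantom i uses seed + i.
#' @param jitter_sd per-artery diameter jitter SD in mm.
#' @param partial_volume segmentation partial-volume fraction (see
#'   \code{\link{makeCowPhantom}}).
#' @return Long data.frame: \code{phantom}, \code{size_mm}, \code{artery},
#'   \code{side}, \code{true_diameter_mm}, \code{diameter_mm},
#'   \code{flags}.
#' @export
cwEnsembleStudy <- function(n_phantoms = 20, sizes = cwResolutions(),
                            seed = 1, jitter_sd = NULL,
                            partial_volume = 0.5) {
  rows <- list()
  for (i in seq_len(n_phantoms)) {
    for (h in sizes) {
      ph <- makeCowPhantom(voxel_mm = h, jitter_sd = jitter_sd,
                           seed = seed + i, partial_volume = partial_volume)
      res <- measureArteries(ph$labelmap)
      rows[[length(rows) + 1]] <- data.frame(
        phantom = i, size_mm = h, artery = res$artery, side = res$side,
        true_diameter_mm = ph$truth$true_diameter_mm,
        diameter_mm = res$diameter_mm, flags = res$flags,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
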