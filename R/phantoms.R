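#' Construct a TubeSpec
#'
#' @param label integer label code.
#' @param points n x 3 matrix of polyline vertices (world mm). A single row
#'   gives a sphere of the tube diameter.
#' @param diameter_mm tube diameter in mm.
#' @return A \linkS4class{TubeSpec}.
#' @export
tubeSpec <- function(label, points, diameter_mm) {
  new("TubeSpec", label = as.integer(label),
      points = matrix(as.numeric(points), ncol = 3),
      diameter = as.numeric(diameter_mm))
}

#' Construct a PhantomSpec
#'
#' @param tubes list of \linkS4class{TubeSpec}.
#' @param fov 2 x 3 matrix, rows (lo, hi), field of view in mm.
#' @param voxel_mm isotropic voxel size.
#' @param vocabulary named character vector, code -> name.
#' @param priority integer label codes in overlap-winning order (earlier
#'   wins); defaults to ascending label codes.
#' @param pv_frac partial-volume emulation margin as a fraction of the voxel
#'   size (default 0 = pure center-in rasterization). See
#'   \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(tubes, fov, voxel_mm, vocabulary = NULL,
                        priority = NULL, pv_frac = 0) {
  labs <- vapply(tubes, function(t) t@label, 0L)
  if (is.null(vocabulary))
    vocabulary <- stats::setNames(paste0("label-", sort(unique(labs))),
                                  as.character(sort(unique(labs))))
  if (is.null(priority)) priority <- sort(unique(labs))
  new("PhantomSpec", tubes = tubes, fov = fov, voxel = voxel_mm,
      vocabulary = vocabulary, priority = as.integer(priority),
      pv_frac = pv_frac)
}

#' Rasterize a phantom onto a voxel grid
#'
#' A voxel receives label L iff its center lies within diameter/2 (plus the
#' spec's partial-volume margin \code{pv_frac * voxel}, default 0) of tube
#' L's centerline polyline. Overlaps are resolved by the spec's priority
#' order (tubes painted in that order, each only into still-empty voxels),
#' so every voxel carries exactly one label. Tubes reaching outside the
#' field of view raise an error.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{LabelMap} with origin at the FOV corner.
#' @export
rasterize <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  lo <- spec@fov[1, ]
  hi <- spec@fov[2, ]
  h <- spec@voxel
  pv <- spec@pv_frac * h
  for (tb in spec@tubes) {
    r <- tb@diameter / 2 + pv
    if (any(sweep(tb@points, 2, lo + r, "<")) ||
        any(sweep(tb@points, 2, hi - r, ">")))
      stop("tube with label ", tb@label, " extends outside the field of view")
  }
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / h - 1e-9)))
  vals <- array(0L, dims)
  ord <- order(match(vapply(spec@tubes, function(t) t@label, 0L),
                     spec@priority))
  for (tb in spec@tubes[ord])
    cpp_paint_tube(vals, dims, rep(h, 3), lo, tb@points,
                   tb@diameter / 2 + pv, tb@label)
  labelMap(vals, spacing = rep(h, 3), origin = lo,
           vocabulary = spec@vocabulary)
}

# stylized planar Circle-of-Willis geometry (world mm): tube endpoints per
# artery, chosen so every junction shares an axis point with its trunk and
# non-communicating segments keep >1.5 mm surface clearance
.cwGeometry <- function(diam, fetal_pca = character(), absent_pcom = character()) {
  seg <- function(name, label, a, b, d)
    list(name = name, label = label, pts = rbind(a, b), d = d)
  g <- list()
  for (s in c("L", "R")) {
    m <- if (s == "L") -1 else 1
    dICA <- diam[[paste0("ICA-", s)]]
    g[[paste0("ICA-", s)]] <-
      seg(paste0("ICA-", s), if (s == "L") 1L else 2L,
          c(m * 8, 2, -6), c(m * 8, 2, 2), dICA)
    g[[paste0("MCA-M1-", s)]] <-
      seg(paste0("MCA-M1-", s), if (s == "L") 6L else 7L,
          c(m * 8, 2, 2), c(m * 14, 2, 2), diam[[paste0("MCA-M1-", s)]])
    g[[paste0("ACA-A1-", s)]] <-
      seg(paste0("ACA-A1-", s), if (s == "L") 4L else 5L,
          c(m * 8, 2, 2), c(m * 2, 6, 2), diam[[paste0("ACA-A1-", s)]])
    if (!(s %in% fetal_pca))
      g[[paste0("PCA-P1-", s)]] <-
        seg(paste0("PCA-P1-", s), if (s == "L") 10L else 11L,
            c(0, -8, 1), c(m * 6, -6, 1), diam[[paste0("PCA-P1-", s)]])
    if (!(s %in% absent_pcom))
      g[[paste0("PCom-", s)]] <-
        seg(paste0("PCom-", s), if (s == "L") 8L else 9L,
            c(m * 8, 2, 0), c(m * 6, -6, 1), diam[[paste0("PCom-", s)]])
    if (s %in% fetal_pca)
      g[[paste0("PCA-P2-", s)]] <-
        seg(paste0("PCA-P2-", s), if (s == "L") 12L else 13L,
            c(m * 6, -6, 1), c(m * 8, -10, 1), diam[[paste0("PCom-", s)]])
  }
  g[["BA"]] <- seg("BA", 3L, c(0, -8, -6), c(0, -8, 1), diam[["BA"]])
  g
}

.cwFov <- function() rbind(c(-17.5, -13.5, -10.5), c(17.5, 9.5, 6.5))

.cwPriority <- function() c(1L, 2L, 3L, 6L, 7L, 4L, 5L, 10L, 11L, 12L, 13L, 8L, 9L)

#' Default artery mean diameters (mm) for the phantom generator
#'
#' Population means for the measured segments: ICA 4.26, ACA A1 2.12,
#' MCA M1 2.71, PCom 1.59, PCA P1 1.96, BA 2.77 mm.
#' @return named numeric vector (by artery code).
#' @export
cwMeanDiameters <- function() {
  c(ICA = 4.26, `ACA-A1` = 2.12, `MCA-M1` = 2.71,
    PCom = 1.59, `PCA-P1` = 1.96, BA = 2.77)
}

#' Default artery diameter population SDs (mm) for the phantom generator
#'
#' Population standard deviations matching \code{\link{cwMeanDiameters}}:
#' ICA 0.62, ACA A1 0.69, MCA M1 0.33, PCom 0.81, PCA P1 0.75, BA 0.51 mm.
#' @return named numeric vector (by artery code).
#' @export
cwDiameterSds <- function() {
  c(ICA = 0.62, `ACA-A1` = 0.69, `MCA-M1` = 0.33,
    PCom = 0.81, `PCA-P1` = 0.75, BA = 0.51)
}

#' Generate a labeled Circle-of-Willis phantom with ground truth
#'
#' Assembles the 11 measured arteries as connected straight tubes in a
#' stylized planar CW layout: each PCom joins the same-side ICA and PCA P1,
#' the M1 and A1 branch from the ICA top, and the P1 segments branch from
#' the basilar tip. Per-artery diameters are the population means of
#' \code{\link{cwMeanDiameters}} plus seeded Gaussian jitter (independent
#' per side), truncated below at 0.8 mm. Variant flags:
#' \code{"fetal_pca_left"}/\code{"fetal_pca_right"} remove the P1 segment,
#' enlarge the same-side PCom (mean 2.2 mm) and continue it into a PCA P2
#' tube so the PCom connectivity rule still holds;
#' \code{"absent_pcom_left"}/\code{"absent_pcom_right"} remove the PCom.
#'
#' @param voxel_mm isotropic rasterization voxel size (mm).
#' @param variants character vector of variant flags (see above).
#' @param jitter_sd per-artery diameter jitter SD: \code{NULL} (default)
#'   uses the population SDs of \code{\link{cwDiameterSds}}, a scalar applies
#'   one SD to every artery, 0 gives the population means exactly. Draws are
#'   truncated to mean +/- 2.5 SD and below at 0.8 mm (non-physical and
#'   out-of-layout diameters excluded).
#' @param seed integer seed for the jitter (reproducible phantoms).
#' @param partial_volume segmentation partial-volume margin as a fraction of
#'   the voxel size (default 0.5: a voxel is segmented as vessel when its
#'   center lies within half a voxel of the true surface, emulating
#'   bright-blood masks that include any voxel the vessel touches; the
#'   resulting dilation scales with voxel size, the partial-volume effect).
#' @param world_offset numeric(3) rigid translation of the anatomy within
#'   the field of view (mm), or \code{NULL} (default) for a seeded uniform
#'   draw in [0, 1) mm per axis -- real anatomy sits at an arbitrary
#'   sub-voxel position relative to the scan grid, so grid alignment must
#'   not be a fixed feature of the ensemble. Drawn after the diameter
#'   jitter, so a given seed fixes both regardless of voxel size.
#' @return list with \code{labelmap} (\linkS4class{LabelMap}), \code{truth}
#'   (data.frame: artery, side, present, true_diameter_mm) and \code{spec}
#'   (\linkS4class{PhantomSpec}).
#' @export
makeCowPhantom <- function(voxel_mm = 0.2083, variants = character(),
                           jitter_sd = NULL, seed = NULL,
                           partial_volume = 0.5, world_offset = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fetal <- c(if ("fetal_pca_left" %in% variants) "L",
             if ("fetal_pca_right" %in% variants) "R")
  nopcom <- c(if ("absent_pcom_left" %in% variants) "L",
              if ("absent_pcom_right" %in% variants) "R")
  mu <- cwMeanDiameters()
  sds <- if (is.null(jitter_sd)) cwDiameterSds()
         else stats::setNames(rep(jitter_sd[1], length(mu)), names(mu))
  arts <- cwMeasuredArteries()
  diam <- list()
  for (r in seq_len(nrow(arts))) {
    nm <- .arteryLabelName(arts$artery[r], arts$side[r])
    base <- if (arts$artery[r] == "PCom" &&
                !is.na(arts$side[r]) && arts$side[r] %in% fetal)
      2.2 else mu[[arts$artery[r]]]
    s <- sds[[arts$artery[r]]]
    jit <- max(min(stats::rnorm(1, 0, s), 2.5 * s), -2.5 * s)
    diam[[nm]] <- max(base + jit, 0.8)
  }
  if (is.null(world_offset)) world_offset <- stats::runif(3, 0, 1)
  geo <- .cwGeometry(diam, fetal_pca = fetal, absent_pcom = nopcom)
  tubes <- lapply(geo, function(s)
    tubeSpec(s$label, sweep(s$pts, 2, world_offset, "+"), s$d))
  spec <- phantomSpec(tubes, .cwFov(), voxel_mm,
                      vocabulary = cwLabelVocabulary(),
                      priority = .cwPriority(), pv_frac = partial_volume)
  truth <- arts
  truth$present <- TRUE
  truth$true_diameter_mm <- NA_real_
  for (r in seq_len(nrow(truth))) {
    nm <- .arteryLabelName(truth$artery[r], truth$side[r])
    absent <- (truth$artery[r] == "PCA-P1" && !is.na(truth$side[r]) &&
                 truth$side[r] %in% fetal) ||
              (truth$artery[r] == "PCom" && !is.na(truth$side[r]) &&
                 truth$side[r] %in% nopcom)
    truth$present[r] <- !absent
    truth$true_diameter_mm[r] <- if (absent) NA_real_ else diam[[nm]]
  }
  list(labelmap = rasterize(spec), truth = truth, spec = spec)
}

#' Two parallel tubes with a controlled surface gap ("kissing arteries")
#'
#' Rasterizes two straight parallel tubes carrying the same label with a
#' given surface-to-surface gap. With gap below one voxel the tubes fuse
#' into a single 26-connected component and the merged mask inflates the
#' apparent diameter; with a gap of several voxels they stay distinct.
#'
#' @param diameters numeric(2), tube diameters in mm.
#' @param gap_mm surface gap between the tubes (>= 0).
#' @param voxel_mm isotropic voxel size.
#' @param length_mm tube length (default 12).
#' @param label label code painted for both tubes.
#' @param isolated if TRUE, rasterize only the first tube on the identical
#'   grid (same field of view and alignment), the matched single-vessel
#'   reference for the kissing comparison.
#' @return A \linkS4class{LabelMap}.
#' @export
makeKissingPair <- function(diameters, gap_mm, voxel_mm, length_mm = 12,
                            label = 2L, isolated = FALSE) {
  stopifnot(gap_mm >= 0, length(diameters) == 2)
  sep <- diameters[1] / 2 + diameters[2] / 2 + gap_mm
  r <- max(diameters) / 2
  fov <- rbind(c(-r - 2, -r - 2, -2),
               c(sep + r + 2, r + 2, length_mm + 2))
  t1 <- tubeSpec(label, rbind(c(0, 0, 0), c(0, 0, length_mm)), diameters[1])
  t2 <- tubeSpec(label, rbind(c(sep, 0, 0), c(sep, 0, length_mm)),
                 diameters[2])
  voc <- stats::setNames("ICA-R", as.character(label))
  tubes <- if (isolated) list(t1) else list(t1, t2)
  rasterize(phantomSpec(tubes, fov, voxel_mm, vocabulary = voc))
}

#' S-shaped (carotid-siphon-like) centerline polyline
#'
#' Two opposed semicircular arcs in the x-z plane whose limbs run parallel
#' at a distance of twice the bend radius; useful for constructing
#' self-approaching curved tubes.
#'
#' @param bend_radius_mm arc radius (mm).
#' @param n points per arc.
#' @return An (2n x 3) polyline matrix.
#' @export
siphonPolyline <- function(bend_radius_mm = 4, n = 40) {
  R <- bend_radius_mm
  th <- seq(-pi / 2, pi / 2, length.out = n)
  a1 <- cbind(R * cos(th), 0, R + R * sin(th))       # lower arc, opens left
  a2 <- cbind(-R * cos(rev(th)), 0, 3 * R + R * sin(rev(th)))
  rbind(a1, a2[-1, , drop = FALSE])
}

#' Simulate a manual rater over phantom ground truth
#'
#' Each present artery is measured as truth plus Gaussian noise (truncated
#' below at 0.1 mm) and independently recorded as missing with the
#' per-artery miss probability; absent arteries are recorded as missing.
#'
#' @param truth ground-truth data.frame (artery, side, present,
#'   true_diameter_mm) as from \code{\link{makeCowPhantom}}.
#' @param noise_sd_mm measurement noise SD in mm (default 0.5, typical
#'   intra-rater variability).
#' @param miss_prob scalar or named vector (by artery code) of probabilities
#'   that a present artery goes unrecorded.
#' @param seed integer seed.
#' @param participant_id identifier for the emitted rows.
#' @return A measurement table (source \code{"manual"}).
#' @export
simulateRater <- function(truth, noise_sd_mm = 0.5, miss_prob = 0,
                          seed = NULL, participant_id = "phantom") {
  stopifnot(noise_sd_mm >= 0, all(miss_prob >= 0), all(miss_prob <= 1))
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(names(miss_prob)))
    rep(miss_prob[1], nrow(truth))
  else {
    pp <- miss_prob[truth$artery]
    pp[is.na(pp)] <- 0
    pp
  }
  d <- rep(NA_real_, nrow(truth))
  for (r in seq_len(nrow(truth))) {
    if (!truth$present[r]) next
    if (stats::runif(1) < p[r]) next
    d[r] <- max(truth$true_diameter_mm[r] + stats::rnorm(1, 0, noise_sd_mm),
                0.1)
  }
  measurementTable(data.frame(
    participant_id = participant_id, artery = truth$artery,
    side = truth$side, diameter_mm = d, source = "manual",
    stringsAsFactors = FALSE))
}
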