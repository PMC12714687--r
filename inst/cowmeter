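#!/usr/bin/env Rscript
# Thin command-line wrapper over the cowmeter package.
#
#   cowmeter resample  --in seg.nii.gz --iso 0.3125 --out out.nii.gz
#   cowmeter thickness --in mask.nii.gz --out lt.nii.gz
#   cowmeter centerline --in seg.nii.gz --out skel.nii.gz
#   cowmeter measure   --in seg.nii.gz --out auto.csv [--participant ID]
#   cowmeter resample-study --in seg.nii.gz --sizes 0.2083,...,0.625 --out-dir d/
#   cowmeter phantom   --voxel 0.2083 --seed 7 --out-prefix phantom/cw
#   cowmeter validate  --manual manual.csv --auto auto.csv --out report.json

suppressPackageStartupMessages(library(cowmeter))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) stop("usage: cowmeter <command> [--flag value ...]")
cmd <- argv[1]
opts <- list()
i <- 2
while (i < length(argv) + 1) {
  if (startsWith(argv[i], "--")) {
    opts[[substring(argv[i], 3)]] <- argv[i + 1]
    i <- i + 2
  } else i <- i + 1
}
req <- function(name) {
  if (is.null(opts[[name]])) stop("missing required flag --", name)
  opts[[name]]
}

writeFloatNifti <- function(grid, path) {
  img <- RNifti::asNifti(structure(gridValues(grid),
                                   pixdim = gridSpacing(grid)))
  RNifti::writeNifti(img, path, datatype = "float")
}

switch(cmd,
  resample = {
    lm <- readLabelMap(req("in"))
    writeLabelMap(resampleNearest(lm, as.numeric(req("iso"))), req("out"))
  },
  thickness = {
    lm <- readLabelMap(req("in"))
    writeFloatNifti(localThickness(lm), req("out"))
  },
  centerline = {
    lm <- readLabelMap(req("in"))
    cls <- centerlinePoints(labelCenterlines(lm))
    out <- array(0L, dim(lm))
    for (code in names(cls))
      if (nrow(cls[[code]])) out[cls[[code]]] <- as.integer(code)
    writeLabelMap(labelMap(out, spacing = gridSpacing(lm),
                           origin = gridOrigin(lm),
                           vocabulary = labelVocabulary(lm)), req("out"))
  },
  measure = {
    lm <- readLabelMap(req("in"))
    tab <- measureAll(lm, participant_id = if (is.null(opts$participant))
      "participant" else opts$participant)
    writeMeasurements(tab, req("out"))
  },
  `resample-study` = {
    lm <- readLabelMap(req("in"))
    sizes <- as.numeric(strsplit(req("sizes"), ",")[[1]])
    dir.create(req("out-dir"), showWarnings = FALSE, recursive = TRUE)
    st <- resolutionStudy(lm, sizes)
    for (nm in names(st))
      writeMeasurements(st[[nm]], file.path(req("out-dir"),
                                            paste0("auto_", nm, ".csv")))
  },
  phantom = {
    ph <- makeCowPhantom(voxel_mm = as.numeric(req("voxel")),
                         seed = as.integer(req("seed")))
    prefix <- req("out-prefix")
    dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
    writeLabelMap(ph$labelmap, paste0(prefix, ".nii.gz"))
    utils::write.csv(ph$truth, paste0(prefix, "_truth.csv"),
                     row.names = FALSE)
  },
  validate = {
    man <- readMeasurements(req("manual"))
    aut <- readMeasurements(req("auto"))
    rep <- buildReport(man, list(auto = aut))
    jsonlite::write_json(rep, req("out"), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  },
  stop("unknown command: ", cmd)
)
invisible(NULL)
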