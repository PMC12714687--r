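Package: cowmeter
Title: Artery Diameter Measurement on Labeled Circle-of-Willis Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures intracranial artery diameters from labeled 3D
    segmentation volumes of the Circle of Willis. Computes per-voxel local
    thickness (largest inscribed sphere), extracts per-artery centerlines by
    topology-preserving 3D thinning, and averages thickness along each
    centerline to yield one diameter per artery. Includes nearest-neighbor
    isotropic resampling for voxel-size sensitivity studies, digital tubular
    phantoms with analytic ground truth and a simulated manual rater, and a
    method-agreement toolkit (detection confusion and ROC, paired-difference
    thresholds, Wilcoxon signed-rank margin tests with Bonferroni correction,
    Spearman correlation, regression summaries, Shapiro-Wilk normality).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
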