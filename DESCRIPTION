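Package: lungct
Title: Automated Quantification of Aerated Lung Volume in Mouse Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated analysis of reconstructed mouse thorax
    micro-computed tomography for quantifying aerated lung volume, an
    imaging surrogate of pulmonary fibrosis (volume loss) and emphysema
    (volume gain). Provides two-point Hounsfield-unit calibration from a
    water/air phantom, retrospective respiratory gating of projections
    into four phase bins, a morphological segmentation algorithm
    (air thresholding, 2D despeckle of enclosed pores, body-ROI
    shrink-wrap with border erosion, largest-3D-component sweep),
    end-inspiratory/end-expiratory volume bookkeeping, post-sacrifice
    pressure-volume curves with trapezoidal area under the curve, and the
    accompanying statistics: Bland-Altman repeatability (within-subject
    SD and 95% repeatability coefficient), agreement regression with
    prediction bands, Welch t-tests, and noncentral t/F power and
    sample-size calculations. A seeded digital thorax phantom with known
    ground truth makes the whole pipeline testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tiff, png, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, pracma, igraph, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
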