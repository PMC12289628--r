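Package: ctmorph
Title: Micro-CT Morphometry of Soil Pore Networks and Xylem Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for 3D X-ray micro-CT volumes of soil
    cores and woody stems: histogram-valley (parabola) global thresholding,
    cylindrical region-of-interest cropping, seeded region growing and phase
    arithmetic; 26-connected component labeling with smoothed surface-area
    estimation, shape-factor and size classification of pores, and
    water-filled pore proportions; medial-axis skeletonization with
    branch/node morphometrics (number, branch, surface-area and node
    densities, mean angle, coordination number, hydraulic radius,
    tortuosity); xylem vessel hydraulics (hydraulic diameter, D95,
    Hagen-Poiseuille conductivities, embolism rate); and the statistical
    layer (Shapiro-Wilk, one-way ANOVA with Fisher's protected LSD and
    compact letter display, Pearson correlation, univariate regression).
    Includes a synthetic phantom generator with ground truth so the whole
    chain is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
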