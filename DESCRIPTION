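Package: afsim
Title: In-Silico Atrial Fibrillation on Left-Atrial Surface Meshes with
    Dominant-Frequency Mapping and Virtual Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monodomain simulation of atrial fibrillation (AF) on
    left-atrium-like triangulated surface meshes using the Courtemanche
    human atrial ionic model with AF electrical remodeling. Provides
    synthetic left-atrial geometry generation with pulmonary-vein ostia,
    mitral annulus and appendage, partitioning into ten anatomical
    sections, conduction-velocity calibration, ramp-pacing AF induction,
    per-node dominant-frequency (DF) mapping by FFT, extraction of
    high-DF areas, virtual catheter ablation with rhythm-outcome
    classification, and the accompanying nonparametric statistics
    (temporal coefficient of variation, Friedman, Kruskal-Wallis,
    Welch t, chi-square).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
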