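Package: cardiofib
Title: Fibrosis Heterogeneity Quantification and Image-Based Bidomain
    Simulation of Ventricular Conduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the composition and microscopic heterogeneity of
    cardiac fibrosis from segmented tissue-label images, classifies heart
    failure etiology (ischemic versus nonischemic cardiomyopathy) from
    fibrosis features by restarted k-means clustering, and simulates 2D
    anisotropic electrical conduction on image-derived meshes with a
    bidomain model coupled to a human ventricular myocyte ionic model.
    Includes a seeded synthetic-tissue generator emulating donor, ischemic
    and nonischemic fibrosis patterns, conduction-velocity vector and tilt
    analysis, and the statistical reporting layer (Welch t, one-way ANOVA,
    variance F tests, linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
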