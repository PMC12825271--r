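Package: safconn
Title: Short-Range Association Fiber Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies short-range association fiber (U-fiber) connectivity
    from streamline tractograms and volumetric cortical parcellations, and
    studies how diffusion-MRI spatial resolution degrades it. Builds
    association-fiber connectomes from TCK tractograms, derives the binary
    "borders-on" cortical adjacency matrix from labelled volumes, computes the
    global and regional Short-range Connectivity Fraction (GSCF/RSCF) with
    intra-regional and length-threshold variants, simulates resolution loss by
    k-space truncation with apodization and spline re-up-sampling, and runs the
    paired within-subject statistical framework (Shapiro-Wilk gated paired
    t/Wilcoxon tests with Benjamini-Hochberg FDR correction). A synthetic-data
    module generates parcellation ribbons, U-fiber tractograms, multi-subject
    multi-resolution connectome ensembles, band-limited phantoms and noisy b=0
    series with analytically known ground truth, so the whole pipeline is
    testable without MRI acquisitions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
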