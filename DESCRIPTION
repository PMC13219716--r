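Package: pavecell
Title: Pavement-Cell Shape Quantification and Mass-Spring Morphogenesis Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the shape of plant epidermal pavement
    cells from polygonal contours and for simulating the emergence of
    jigsaw-puzzle cell shapes under time-varying anisotropic tissue growth.
    Implements per-cell shape descriptors (area, perimeter, lobeyness,
    min-axis, largest empty circle), contour cleaning and labeled-tree I/O,
    a fully damped mass-spring model of boundary-driven tissue growth with
    geometric placement of microtubule-proxy connections and optional early
    cell division, cross-species survey statistics (per-species Pearson
    correlation, percentile selection, origin-constrained quadratic fits,
    exact binomial sign aggregation), and synthetic contour generators with
    controlled statistical structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
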