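Package: bmpgrad
Title: Quantify BMP/pSmad5 Gradients and Expression Boundaries in Zebrafish Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of how the BMP signalling
    gradient (read out as nuclear phosphorylated Smad5) patterns the
    dorsal-ventral axis of the zebrafish gastrula.  Includes a synthetic
    embryo generator with known ground truth (monotone Hermite gradient
    profiles for wild-type, chordin-mutant and bmp7-null genotypes,
    threshold/slope/duration gene readout models, dissociated-cell dose
    assays and ligand-pulse experiments), spherical geometry for nuclear
    point clouds (sphere fitting, axis registration, angular coordinates,
    triangular surface patches), angular intensity profiles with locally
    weighted smoothing and slope estimation, expression-boundary calling
    at a fraction of maximum intensity with pSmad5 level and slope
    readouts, DV expression-domain clustering from 8x8 heat maps, and
    statistical discrimination between threshold, slope and duration
    models of gradient interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
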