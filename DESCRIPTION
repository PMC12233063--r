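Package: hexeye
Title: Complete Segmentation of Ommatidia in Drosophila Compound Eye Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase segmentation of every visible ommatidium (facet) in 2D
    images of fruit fly compound eyes. Phase one trains pixel-level random
    forest classifiers from sparse annotations and converts images into
    probability maps of the eye region and the facet surfaces; phase two
    expands a hexagonal grid one ommatidium at a time by mirroring registered
    neighbor triplets and fitting a three-circle template to the facet
    probability map, assigning each facet a unique integer hexagonal
    coordinate. Includes focus stacking of multifocal brightfield stacks with
    depth-derived facet altitude, morphometric analytics (total counts,
    anterior-posterior column profiles, smoothed 3D inter-ommatidial spacing
    maps, cross-eye averaging), and a ground-truthed synthetic compound-eye
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ranger,
    tiff,
    png,
    jsonlite,
    mgcv,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
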