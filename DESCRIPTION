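Package: nucmorph
Title: Automated Nuclear Shape Analysis from Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, high-throughput quantification of nuclear morphology
    from fluorescence microscopy images of lamin-stained nuclei. Extracts
    sub-pixel nuclear boundaries with a gradient-vector-flow (GVF) active
    contour initialized on per-nucleus convex hulls, computes signed boundary
    curvature by local circle fitting, and summarizes blebbing with the mean
    negative curvature (MNC) statistic alongside a panel of shape and
    intensity measures (area, perimeter, eccentricity, solidity, tortuosity,
    invagination count). Provides population-level curvature heat maps,
    metric correlation clustering, one-tailed unequal-variance group tests,
    and a synthetic nucleus image generator with analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    pracma,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
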