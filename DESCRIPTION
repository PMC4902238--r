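Package: rhodoscan
Title: Image-Based Stress Quantification for Rhodolith-Forming Calcareous Algae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn laboratory photographs of rhodolith-forming calcareous
    algae into quantitative stress measurements. Images carrying a six-circle
    color reference plate are corrected for illumination, per-channel gamma and
    camera zoom; pixels are classified as live algae with a hierarchically grown
    hyperbolic self-organizing map (H2SOM) whose prototypes are labelled from
    sparse expert annotations; segmented regions are measured (zoom-weighted
    size, circular-mean hue, saturation, value) and related to experimental
    factors (light, flow, sediment, time) by cross-validated PLS2 regression.
    Includes a synthetic-scene generator with full ground truth so the whole
    pipeline is testable without the original image archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
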