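Package: fluoroseg
Title: Color-Based Tooth Segmentation and Dental Fluorosis Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automatic segmentation and severity staging of dental
    fluorosis from color photographs of the anterior teeth.  Pixels are
    described by six color features (RGB plus HSI), clustered with
    unsupervised possibilistic fuzzy clustering (UPFC) into labeled
    multi-prototypes, with the number of clusters chosen by a cuckoo
    search over cross-validated classification accuracy.  Fuzzy
    k-nearest-neighbor classification against the prototypes yields a
    five-class pixel map, a binary tooth mask, and the proportions of
    opaque-white and brown enamel pixels, from which a rule-based
    classifier grades fluorosis into Normal and Stages 1-3.  Includes a
    synthetic mouth-image generator with known ground truth for testing
    and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
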