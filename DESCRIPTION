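Package: accbehave
Title: Behaviour Classification for Broiler Chickens from Tri-Axial Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying sitting, standing and walking behaviour of
    broiler chickens from tri-axial accelerometer recordings. Decomposes raw
    acceleration into static (gravitational) and dynamic (movement) components with
    zero-phase Butterworth filters, derives VeDBA and tilt angles, computes 99
    attributes over 3-second sliding windows with 50% overlap, labels windows by
    behavioural purity against annotated intervals, builds strain-stratified
    bird-level train/test splits with minority-class upsampling, ranks attributes by
    information gain with MDL supervised discretisation, trains and cross-validates
    random forests, and evaluates predictions with confusion matrices and per-class
    and micro-aggregated accuracy, sensitivity, specificity and precision. Includes
    a synthetic flock generator with per-strain behavioural bout statistics so the
    full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
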