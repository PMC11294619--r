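Package: nigraquant
Title: Quantitative Post-Mortem Image Analysis of Nigral Dopaminergic Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for quantitative post-mortem neuropathology:
    per-cell detection and subcellular localisation (perinuclear versus
    cytosolic) of lysosomal-related fluorescent puncta inside labelled-neuron
    masks; unbiased-counting-frame stereology with the optical fractionator;
    DAB densitometry (mean grey level and thresholded surface ratio) and
    elemental-map region averaging; and two-group estimation statistics
    (unpaired t-tests, bootstrapped mean differences with confidence
    intervals for Gardner-Altman estimation plots, and control-referenced
    z-score profiles). A synthetic-data generator with known ground truth
    emulates the image and measurement structure of such studies and serves
    as the validation oracle for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
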