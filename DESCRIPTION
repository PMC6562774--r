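Package: scalocnn
Title: Scalogram-Based Convolutional Neural Network Classification of EEG Segments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects epileptic activity in single-channel EEG segments by
    converting each segment to a Morlet continuous-wavelet-transform scalogram,
    resizing the time-frequency energy image to 32x32 pixels by cubic
    interpolation, and classifying the images with a small two-convolution-layer
    neural network under stratified 10-fold cross-validation. Includes a reader
    for the plain-text single-column EEG dialect used by the public Bonn
    epilepsy corpus, a seeded synthetic EEG generator with class-distinct
    time-frequency structure (background rhythms, interictal spikes, ictal
    discharge), the full confusion-matrix metric suite with every published
    labelling convention, and a command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
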