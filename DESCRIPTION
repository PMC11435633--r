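Package: dfcgn
Title: Graph-Convolutional Emotion Recognition from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for EEG-based emotion recognition over a small channel
    connectivity graph. Generates seeded synthetic music-stimulus EEG
    sessions with class-dependent spectral signatures, implements the
    preprocessing chain (channel selection, mid-song extraction, per-class
    stacking, fixed windowing, stratified splits and sample-budget
    bookkeeping), a 1-D convolutional generative adversarial network for
    data augmentation, spectral graph machinery (graph Fourier transform,
    Laplacian eigensystem, Chebyshev polynomial filtering), a four-layer
    graph-convolutional classifier trained by backpropagation, and a full
    evaluation suite (confusion-matrix indices, Cohen's kappa, ROC,
    stratified k-fold, leave-one-subject-out, noise-robustness sweeps and
    handcrafted-feature baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    nnet,
    class,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
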