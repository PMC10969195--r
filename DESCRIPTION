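Package: sttcnn
Title: Spatial-Temporal Transformer and CNN Models for EEG Emotion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies emotional state from raw segmented multichannel EEG with a
    dual-branch transformer network: one encoder attends across channels (the
    spatial arrangement of the signal), a parallel encoder attends across time
    points (the temporal arrangement), and a small convolutional head fuses the
    two feature maps before a softmax classifier. Includes the three ablation
    variants of the architecture (no convolutional head, spatial branch only,
    temporal branch only), sinusoidal positional encoding, multi-head scaled
    dot-product attention and backpropagation implemented in base R, Adam
    training with cross-entropy plus L2 loss, stratified k-fold cross-validation,
    accuracy/precision/recall/F1 reporting with model-comparison t-tests, a
    class-conditional synthetic EEG generator with separately plantable spatial
    and temporal discriminative signal, EDF and binary matrix-container I/O, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
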