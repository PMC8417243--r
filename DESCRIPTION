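Package: seizecast
Title: Seizure Prediction from Multichannel EEG via Wavelet-Packet Band
    Energies, Chebyshev Graph Convolution and Gated Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pre-ictal versus inter-ictal scalp EEG windows for
    seizure prediction. Each multichannel window is decomposed with a
    depth-4 wavelet packet transform into 16 sub-band energies per channel;
    channels become nodes of a functional-connectivity graph weighted by
    Pearson correlation; a Chebyshev-polynomial spectral graph convolutional
    encoder maps each window to a per-channel status code; and a gated
    recurrent unit with a multilayer-perceptron head classifies
    chronologically ordered status-code sequences. Includes EDF input with
    seizure annotations and the 1 h to 5 min pre-ictal labeling rule,
    overlapping-window segmentation, a synthetic multichannel EEG generator
    with planted sub-band-energy and cross-channel-correlation class
    structure, end-to-end training (Adam, cross-entropy + L2), and a
    per-case sensitivity/specificity/PPV/NPV/FPR/accuracy/F1 metric suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
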