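Package: silentspeech
Title: Few-Shot Silent Speech Recognition from Single-Channel EMG and EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Sentence-level silent speech recognition from single-channel
    electromyography (EMG) and electroencephalography (EEG) time series.
    Implements a few-shot Siamese 1-D convolutional encoder trained with a
    contrastive loss over cosine distance, a 5-shot per class reference set,
    moving-window segmentation and positional labeling of continuous sentence
    signals, parallel multi-layer EMG+EEG sensor fusion, and trigram
    language-model filtering and re-ranking of decoded word sequences.
    Includes a seeded synthetic biosignal generator emulating isolated-word
    and coarticulated-sentence corpora so the full pipeline is testable
    without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
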