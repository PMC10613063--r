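Package: popdecode
Title: Population Decoding and Encoding of Natural Movie Frames from Binned Spiking Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess visual coding in binned population spiking data:
    linear support-vector decoding of natural-movie frames (binary pairwise and
    one-vs-all multi-class), quantification of how behavioural-state mismatch
    between training and test repeats degrades decoding, a two-stage
    log-link generalised linear encoding model with a stimulus-by-running-speed
    interaction, and reconstruction of "decoder receptive fields" (W.A.M) with
    correlation-based similarity analysis. Ships a synthetic-session generator
    (frame-tuned Poisson spiking, bimodal locomotion, selectable behavioural
    modulation) so the full pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
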