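Package: qrsdistill
Title: Universal Multi-Lead QRS Detection by Leads Distillation and a
    Lightweight U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects QRS complexes in electrocardiograms with any number of
    leads. A leads-distillation module learns per-sample attention weights
    across leads (sigmoid squeeze followed by a column-wise softmax) and
    collapses an L-lead window into a single distilled signal; a small
    1-D U-Net segments QRS complexes in that signal. A paired scaling
    operation (stride decimation of the input, nearest-value upsampling of
    the output) shortens the signal the network sees and discards
    high-frequency content that hampers detection. Includes band-pass
    preprocessing, QRS label construction at any sampling frequency,
    dice-loss training with Adam, beat-by-beat evaluation with the AAMI
    75 ms matching rule (sensitivity, positive predictivity, F1), a
    synthetic multi-lead ECG generator with known R-peak ground truth, a
    minimal WFDB reader/writer, and desk-scale experiment drivers for the
    scaling-factor scan and its spectral explanation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
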