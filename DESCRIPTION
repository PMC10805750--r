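Package: ecg2ppg
Title: ECG-to-PPG Waveform Translation with Adversarial U-Nets and an
    Atrial-Fibrillation Validation Harness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for synthesizing photoplethysmogram (PPG) waveforms from
    paired single-lead electrocardiogram (ECG) segments with a 1-D U-Net
    generator trained against a Markovian (patch) discriminator, together
    with the surrounding pipeline: a seeded simulator of paired sinus-rhythm
    and atrial-fibrillation waveform records, Pan-Tompkins R-peak detection
    and peak-interval quality control, fixed-window segmentation and
    sliding-window slicing, morphology and rhythm agreement metrics (percent
    root-mean-square difference, Pearson correlation, beat-by-beat heart
    rate comparison), an exact t-SNE embedding with a kernel-density
    Degree-of-Overlap statistic between embedded populations, and a compact
    convolutional atrial-fibrillation classifier used to measure the value
    of generated PPG as training data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
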