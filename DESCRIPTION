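Package: pcgbeam
Title: Microphone-Array Beamforming and Nonlinear Analysis of Diastolic
    Heart Sounds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of the acoustic signature of coronary artery
    stenosis in multichannel phonocardiograms.  Implements time-delay
    (delay-and-sum) beamforming of a small chest-surface microphone array
    with sub-sample delay alignment and SNR-gain evaluation, isolation of
    128-ms diastolic windows referenced to the second heart sound,
    approximate-entropy and 150-Hz band-energy-ratio features of the
    isolated windows, and one-way analysis of variance of the features
    across pre-stent, post-stent and normal groups.  A seeded synthetic
    phonocardiogram generator with full ground-truth annotations provides
    validated inputs for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
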