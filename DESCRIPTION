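Package: emgfatigue
Title: Surface EMG Muscle-Fatigue Analysis for Isometric and Isotonic Contractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for single-channel surface electromyography
    (EMG) recordings aimed at muscle-fatigue assessment: Butterworth band-pass
    and mains comb-notch filtering, ADC-quantization emulation, maximal
    voluntary contraction (MVC) estimation and percent-MVC normalization,
    windowed time- and frequency-domain feature extraction (RMS, median and
    mean power frequency, and their short-time instantaneous counterparts for
    cyclic contractions), Spearman trend-based fatigue classification, and
    nonparametric device-agreement statistics. Includes a synthetic EMG
    generator with programmable amplitude and spectral-centroid trajectories,
    cyclic contraction envelopes, mains contamination, and quantization, plus
    WAV/CSV input and output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'emgfatigue-package.R'
    'fatigue-stats.R'
    'features.R'
    'mvc.R'
    'preprocess.R'
    'signal-io.R'
    'utils.R'
    'synth.R'
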