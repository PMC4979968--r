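Package: tcdsim
Title: Thalamo-Cortical Network Simulation and EEG Spectral Analysis of
    Stroke-Induced Dysrhythmia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a thalamo-cortical spiking network in which a focal
    cortical lesion deafferents thalamic nuclei, hyperpolarises relay cells,
    de-inactivates T-type calcium channels and switches them from tonic firing
    to low-threshold calcium-spike bursting (thalamo-cortical dysrhythmia).
    Thalamic nuclei are integrate-and-fire-or-burst neurons; the cortical sheet
    is a quadratic integrate-and-fire (Izhikevich) network. Includes lesion
    cohort protocols, inter-spike-interval burst statistics, Morlet-wavelet
    time-frequency decomposition with canonical EEG band summaries, a
    resting-state EEG preprocessing pipeline (bandpass, common-average
    reference, artifact-free epoching, electrode mirroring, rank-sum group
    comparison), and a synthetic multichannel EEG generator with 1/f
    background, subject-specific alpha rhythm and transient artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
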