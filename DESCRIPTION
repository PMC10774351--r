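Package: vividEEG
Title: Oscillatory EEG Power and the Subjective Vividness of Imagined Experiences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking oscillatory EEG power to the subjective
    intensity of imagined audio and visual experiences. Provides a synthetic
    cohort generator with 1/f background spectra, alpha peaks, occipitally
    weighted condition effects and band-limited vividness couplings;
    zero-phase Butterworth preprocessing (band-pass, notch, average reference,
    centred epoching, amplitude-range artifact exclusion); 1 Hz-binned
    periodogram power spectral density features (1-40 Hz); a per-participant
    leave-one-trial-out nearest-neighbour condition decoder with a shuffle
    test; group-level cluster-based permutation tests over sensor-by-frequency
    space; per-frequency linear support vector regression of vividness ratings
    against a shuffled-label chance distribution; and Jeffreys-Zellner-Siow
    Bayes-factor t-tests. An end-to-end pipeline orchestrates all stages from
    a single seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
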