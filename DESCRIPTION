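Package: tfdinfo
Title: Information-Complexity Features of Time-Frequency Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes information-theoretic features of acoustic signals from
    spectra, spectrograms and reassigned spectrograms: Shannon and Renyi
    entropies, disequilibria (Euclidean, total-variation, Jensen-Shannon and
    geometric-mean Renyi-Jensen-Shannon divergences) and the statistical
    complexities built from them, together with a column-stochastic
    decomposition of the spectrogram and its ergodic (stationary) entropy
    features.  Ships generators for synthetic hydroacoustic model signals
    (harmonic sums, linear FM chirps, cavitation-modulated vessel noise,
    band-limited Gaussian noise) with exact SNR control, and a Monte-Carlo
    detection harness producing AUC-ROC and detection-probability curves over
    SNR sweeps and entropy-complexity (H/C) planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
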