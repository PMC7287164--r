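Package: assrpac
Title: Cross-Frequency Coupling Analysis of Auditory Steady-State Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating event-related phase-amplitude coupling (PAC)
    in epoched electrophysiological recordings of the auditory steady-state
    response (ASSR). Implements Morlet wavelet time-frequency decomposition,
    inter-trial phase coherence, across-trials mean-vector-length PAC with
    segment-swap surrogate z-scoring, stimulus-versus-baseline cluster-based
    permutation testing of comodulograms, and rise-decay waveform-shape
    controls against non-sinusoidal artifacts. Ships a synthetic ASSR session
    generator with configurable theta/alpha-gamma coupling, 1/f background
    noise and oddball paradigm structure, so every analysis stage can be
    validated against known ground truth without recorded MEG data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
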