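Package: ssvepkit
Title: Frequency-Phase Coded SSVEP Speller Simulation and Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for steady-state visual evoked potential (SSVEP)
    brain-computer-interface spellers that encode targets on an equally
    spaced frequency-phase grid. Builds hybrid frequency-phase codebooks
    and sampled-sine stimulus waveforms, forward-simulates multi-channel
    EEG epochs (harmonic SSVEP response over occipital channels plus 1/f
    background noise), decodes epochs with canonical correlation analysis
    against sine-cosine harmonic references including a filter-bank and a
    template-extended variant, and evaluates simulated-online performance
    via leave-one-out cross-validation, classification accuracy, bits per
    selection and the Wolpaw information transfer rate. Reads continuous
    EEG from European Data Format (EDF) files sliced by an event table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
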