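Package: beatssep
Title: Frequency-Tagged Steady-State Evoked Potentials of Imagined Musical Beat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-lab analysis pipeline for EEG frequency tagging of
    imagined musical beat: synthesis of the beat-ambiguous amplitude-modulated
    auditory stimulus, extraction of steady-state evoked potential (SSEP)
    amplitudes from epoched EEG via trial averaging, discrete Fourier
    amplitude spectra and neighbor-bin noise subtraction, per-lab
    repeated-measures statistics with Greenhouse-Geisser correction, random-
    and mixed-effects meta-analysis of raw mean and median condition
    differences across labs, and trial-level logistic regression linking
    neural amplitudes to probe-task behavior. Includes a synthetic multi-lab
    EEG/behavior generator with the statistical structure the analysis
    assumes, and an a priori power routine for the repeated-measures design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    sandwich,
    withr
Config/testthat/edition: 3
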