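Package: meploop
Title: Closed-Loop TMS Motor Evoked Potential Neurofeedback: Simulation
    and Offline Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates operant neurofeedback of transcranial magnetic
    stimulation (TMS) motor evoked potential (MEP) amplitude with a
    generative model of a synthetic participant (sigmoid recruitment
    curve, latent corticomotor excitability with operant learning,
    surface EMG background, state-dependent EEG epochs), and implements
    the complete offline analysis chain: EMG-gated closed-loop trial
    engine with an adaptive reward staircase and sham control schedule,
    MEP cleaning (band-pass filtering, background-EMG exclusion cascade,
    block trimming, baseline normalization), pre-stimulus EEG spectral
    features (Welch periodogram, relative band power, low-gamma to
    high-alpha ratio, 1/f scaling, paired contrasts, trial-wise robust
    regression), cross-validated linear support-vector classification of
    brain states with permutation null and recursive feature
    elimination, and paired-pulse TMS protocols (SICI, LICI, LCD) with
    conditioning-stimulus search and state-dependence contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
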