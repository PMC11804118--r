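Package: epilfp
Title: Epileptiform Spike Detection and Synchrony Analysis for LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless analysis of local field potential (LFP) recordings from
    epilepsy animal models. Provides adaptive three-threshold epileptiform
    spike detection (a per-window moving amplitude threshold, a fixed
    amplitude floor, and a refractory minimum inter-spike distance),
    zero-phase FIR and Butterworth bandpass filtering, spike-morphology
    slope metrics from the averaged spike waveform, inter-channel spike
    coincidence, and Pearson correlation matrices, together with a seeded
    synthetic LFP generator with planted ground truth for validation and a
    command-line entry point. Results are tibbles and S3 objects with
    tidy(), glance() and autoplot() methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
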