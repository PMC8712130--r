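Package: vwmeeg
Title: Dual-Modality n-Back EEG Analysis of Verbal Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a dual-modality (auditory/visual) n-back
    verbal working-memory experiment in children: task protocol generation and
    behavioural scoring (accuracy, reaction time, inverse efficiency score),
    synthetic multichannel EEG with known ground truth, preprocessing with
    explicit amplitude/trend/jump artifact criteria, individual-alpha-frequency
    (IAF) relative band power via Welch spectra, the Beta/(Alpha+Theta)
    engagement index, and a 2x3 load-by-modality repeated-measures ANOVA with
    Duncan's multiple range test and partial eta squared effect sizes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
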