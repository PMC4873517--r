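Package: pdcnet
Title: Effective Brain Networks from EEG via Partial Directed Coherence and Graph Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An analysis pipeline for directed (effective) brain connectivity
    from multichannel EEG. Recordings are down-sampled and cut into sliding
    windows; electrodes are screened by local mean decomposition (LMD) energy
    features and leave-one-out classification; per-window multivariate
    autoregressive (MVAR) models with AIC order selection yield partial
    directed coherence (PDC) spectra, averaged into rhythm-band connectivity
    matrices with bootstrap edge significance; proportional thresholding turns
    these into directed binary graphs whose degree and global/local efficiency
    are contrasted between mental states (play vs. rest) with paired t-tests
    and two-way ANOVA. A synthetic MVAR generator with planted band-specific
    directed coupling exercises the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
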