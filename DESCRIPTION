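Package: lpsnet
Title: Source-Space Lagged Phase Synchronization Network Analysis for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain functional connectivity and network analysis of
    event-related EEG in source space. Implements lagged phase synchronization
    (LPS) connectivity over cortical region-of-interest time series obtained
    with a standardized minimum-norm (sLORETA-style) inverse, baseline
    normalization into event-related connectivity indices, average-linkage
    dendrogram identification of sub-networks, weighted clustering
    coefficients, family-wise-error-controlled permutation inference (paired
    tmax and max-statistic Spearman correlation tests), and response-time
    extraction from EMG. Includes a ground-truthed synthetic-data generator
    (lagged narrowband coupling, volume-conducted scalp mixing, ocular and
    myogenic artifacts, planted behavioral links) plus preprocessing via
    zero-phase band-pass filtering, common-average referencing, SOBI-based
    EOG removal and BSS-CCA EMG removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
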