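Package: rigorephys
Title: Quality Control and Cross-Laboratory Reproducibility Statistics for
    Extracellular Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements recording-inclusion quality-control metrics for
    extracellular electrophysiology (sliding refractory-period contamination
    confidence, amplitude-cutoff false-negative estimate, median spike
    amplitude, yield, AP-band noise, LFP depth profiles) together with a
    statistics suite for assessing reproducibility of neural features across
    laboratories: max-CDF-distance permutation tests with mouse-level
    relabelling, a binary-search power analysis, classifier decoding with
    shuffle nulls, task-modulation window tests and Fano factors,
    PCA embedding of double peri-event time histograms with KS and distance
    permutation tests, outlier and variance-decomposition analyses, and probe
    trajectory targeting-error geometry. A synthetic-data module generates
    multi-lab populations with controllable contamination, truncation and
    per-lab effects so the whole pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    randomForest,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
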