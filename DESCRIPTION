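Package: tepkit
Title: Sham-Controlled TMS-EEG Evoked Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of transcranial magnetic stimulation (TMS)
    evoked EEG potentials with a matched realistic sham control. Provides a
    synthetic multi-participant, multi-session two-condition data generator with
    known planted peripheral (PEP) and transcranial (TEP) evoked components; a
    sensor-space preprocessing chain (baseline correction, robust polynomial
    detrending with evoked-window exclusion, exponential decay-artifact removal,
    pulse-artifact excision with cubic interpolation, anti-aliased resampling,
    average re-referencing, spherical-spline channel interpolation, condition
    averaging and active-minus-sham subtraction); global mean field amplitude
    and data-driven segmentation of the post-stimulus window into time windows
    of interest; inter-session test-retest reliability mapping with the
    concordance correlation coefficient, Fisher z aggregation and sign-flip
    permutation inference with t-max family-wise error control; dependent-samples
    cluster-based permutation contrasts over electrodes and time; and a toy
    minimum-norm source projection on an analytic three-shell spherical head
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    rhdf5,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
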