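Package: olivosync
Title: Complex-Spike Synchrony and Cerebellar Nuclear Firing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-electrode recordings of cerebellar
    Purkinje cell complex spikes (CS) and deep cerebellar nuclear (DCN)
    neurons. Identifies monosynaptically connected PC-DCN pairs from
    CS-triggered crosscorrelograms (two-regression slope test), quantifies
    pairwise CS synchrony with the zero-lag correlation coefficient C(0) of
    binarized spike trains, assigns per-CS synchrony levels within a +/-5 ms
    window, measures short-latency inhibition and long-latency excitation of
    DCN firing as functions of synchrony level, tests the spatial restriction
    of presynaptic groups by permutation, and characterizes the dependence of
    inhibition on the temporal precision of synchrony via expanding-window
    (cusum/donut) analysis. Includes a seeded generator of olivocerebellar
    spike trains with ground truth so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
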