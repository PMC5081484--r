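Package: rtpquant
Title: Absolute Protein Quantification from PRM Spike-In Data and
    RNA-to-Protein Conversion Factors
Version: 0.1.0
Authors@R:
    person("rtpquant", "maintainers", email = "rtpquant@example.org",
           role = c("aut", "cre"))
Description: Rolls transition-level parallel-reaction-monitoring (PRM)
    measurements with heavy spike-in peptide standards up to absolute
    protein copies per cell, using the four core histones as a
    proteomic-ruler cell count for lysates where direct counting is
    impossible.  Pairs the resulting copy-number matrix with RNA
    abundance (TPM) to estimate gene-specific RNA-to-protein (RTP)
    conversion factors, predicts protein copy numbers from RNA by
    leave-one-out, and characterises prediction robustness as a function
    of training-set size by resampling cross-validation.  Includes a
    synthetic-data generator emulating the statistical structure of a
    multiplexed PRM study (heavy/light fragment areas, histone anchors,
    log-normal noise, gene-sample dropouts) so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
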