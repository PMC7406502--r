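Package: nbsconn
Title: Intrinsic Connectomes and Network-Based Statistics for Treatment-Outcome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connectome-wide analysis of intrinsic functional
    connectivity in clinical treatment studies. Builds Fisher-z functional
    connectomes from parcel-level fMRI time series (nuisance regression with
    task covariates and a Volterra motion expansion, motion censoring,
    band-pass filtering), computes treatment-outcome scores (residualized
    change, responder classification), identifies outcome-associated
    subnetworks with the network-based statistic (permutation max-component
    familywise control), summarizes subnetworks into composite and
    network-pair connectivity metrics with group and group-by-time ANOVAs,
    and quantifies individual-level predictive value with leave-one-out
    cross-validated logistic models. Includes a synthetic-cohort generator
    with planted effects so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
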