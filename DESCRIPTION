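Package: momclose
Title: Exact Moment Closures for Discretely Structured Logistic Growth
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulate compartmental generalisations of logistic growth in
    which a population is stratified over discrete states and all kinetic
    rates (reproduction, death, environmental burden, between-state flux)
    are polynomial in the state index.  Derives the exact evolution
    equations of the population moments, decides whether the moment
    hierarchy closes exactly at a requested order, constructs the
    admissible flux families when a closure exists, and demonstrates how
    state-preserving and state-resetting reproduction can be distinguished
    from aggregated moment trajectories alone.
License: MIT + file LICENSE
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
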