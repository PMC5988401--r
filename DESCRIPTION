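Package: muxvig
Title: Multiplex Visibility Graph Analysis of Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps multivariate time series (such as resting-state fMRI BOLD
    signals averaged over regions of interest) into multiplex visibility
    graphs, one layer per signal, and quantifies within- and between-signal
    dynamical structure. Provides natural and horizontal visibility graph
    construction (brute-force and divide-and-conquer, with an exact
    equivalence contract), interlayer mutual information between layer
    degree sequences averaged within labeled signal groups, Louvain-based
    temporal community detection with Sorensen and normalized mutual
    information comparisons, and robust group-level statistics
    (Harrell-Davis quantiles, Bayesian bootstrap highest-density intervals,
    shift functions, Kolmogorov-Smirnov distances, Holm correction, and
    covariate-adjusted group tests). A synthetic generator of band-limited,
    network-structured cohorts makes the full pipeline testable without any
    neuroimaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
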