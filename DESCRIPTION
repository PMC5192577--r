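Package: chromodyn
Title: Structure and Dynamics of Topologically Independent Chromatin Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytic polymer models of chromatin domains (loop rosettes,
    globules and blobs) linking relaxation-mode spectra to gyration radii and
    genomic content; self-avoiding lattice Monte Carlo simulation of
    loop-cluster chains with contact-probability map generation and
    loop-base detection; fluorescence correlation spectroscopy machinery
    (windowed correlator, diffusion and polymer-relaxation models, window-size
    scanning) that converts intensity fluctuation traces into domain
    relaxation times; FRAP and continuous-photobleaching analysis of a
    sequential two-state chromatin-binding scheme; and an accessible-volume
    model of domains for probes of given size. Includes synthetic-data
    generators with known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
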