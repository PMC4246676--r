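Package: fluxcord
Title: Transcript-Flux Concordance Analysis for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask how far transcript abundance reflects metabolic
    flux in central metabolism, built around a comparison of two contrasting
    genotypes. Implements flux balance and flux variability analysis under
    flux-ratio constraints on stoichiometric models, T/S/N flux
    responsiveness calls, a conditioned negative-binomial exact test for
    differential expression with median-of-ratios normalization and
    method-of-moments dispersion estimation, stringent
    transcript-to-gene-to-reaction call aggregation over gene-protein-reaction
    associations, flux-change-value and +/-1 congruence scoring with
    pathway/compartment-grouped map export, metabolite pool comparison, and a
    synthetic-data generator that emulates the two-accession, three-replicate
    study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
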