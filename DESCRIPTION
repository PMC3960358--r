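Package: ilsim
Title: Simulation of Marker-Assisted Backcrossing Schemes for Introgression Line Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of marker-assisted backcross programs that
    develop introgression-line (IL) populations in a maize-style genome of ten
    200 cM chromosomes. Meiosis follows the Haldane model (Poisson crossovers,
    no interference); crossing schemes cover two or three backcross generations
    followed by doubled-haploid or two-generation selfing line development, with
    region-based marker selection (complete chromosomes, chromosome halves, or
    20 cM target segments) on a selection index that weighs donor content of
    the selection region against recovery of the recipient background. A
    built-in catalogue of crossing schemes with different population-size
    profiles is evaluated over replicated runs with nine population measures
    (donor genome coverage and depth, disjunct genome segments, resolution,
    donor segment counts and lengths, donor genome proportions genome-wide, on
    carrier chromosomes and within target segments) together with
    high-throughput genotyping assay accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
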