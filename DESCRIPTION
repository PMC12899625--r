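Package: sirnadesign
Title: Rational Design of Chemically Modified siRNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the in-silico design of small interfering RNA (siRNA)
    duplexes against a target mRNA. Enumerates candidate duplexes along a
    transcript, applies the published Ui-Tei, Reynolds and Amarzguioui
    first-pass rules, and ranks candidates with a multi-criterion efficacy and
    specificity score combining sequence rules, a nearest-neighbor
    thermodynamic "energy valley" test, a minimum-free-energy target-site
    accessibility test and an off-target homology screen. Includes the X/Y
    energy-class engine for designing 2'-O-methyl / 2'-fluoro chemical
    modification patterns, a grammar for modified-oligonucleotide notation
    strings, and laboratory support calculators: average molecular weight of
    modified oligonucleotides, multi-stage synthesis yield planning and
    delta-delta-Cq relative expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stringr,
    tibble,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
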