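Package: recessiveBurden
Title: Genetic Prevalence and Disease Burden Estimation for Autosomal-Recessive Ultra-Rare Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates birth incidence, carrier counts and current (living-patient)
    prevalence of autosomal-recessive ultra-rare disease from population allele
    frequencies, with rhizomelic chondrodysplasia punctata (RCDP) as the motivating
    application. Pathogenic variants are selected by clinical classification,
    predicted loss of function, or SIFT/PolyPhen-2 concordance; per-gene pathogenic
    allele frequencies are pooled with modified-Wald (Agresti-Coull) confidence
    intervals, converted to genotype and carrier prevalence under Hardy-Weinberg
    equilibrium, scaled by historic birth series, and aged through a discrete
    life table to current prevalence with confidence ranges propagated end to end.
    Includes a synthetic-data generator emulating gnomAD/TopMed-scale allele-count
    extracts, historic birth series, and natural-history survival cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
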