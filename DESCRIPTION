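Package: deintrogress
Title: Marker-Guided Removal of Introgressed Genetic Background by
    Forward Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based forward-in-time simulator and management
    optimizer for de-introgression programs: exogenous individuals enter a
    native population, admix for several generations of random mating, and
    are then purged over generations of managed reproduction guided by
    molecular markers of varying informativeness. Implements truncation
    selection on native-allele counts, optimal-contribution selection by
    simulated annealing over allele-frequency distances (Cavalli-Sforza and
    Edwards chord, Nei minimum, Kullback-Leibler), Hungarian
    minimum-coancestry mate assignment, pedigree inbreeding and coancestry
    bookkeeping, and per-generation metrics (native founder representation,
    inbreeding, observed homozygosity, effective size).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
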