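Package: hostpref
Title: Host Preference and Community Structure of Root-Associated Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for assessing host-plant preference and
    community structure of root-associated fungi from amplicon survey data.
    Implements a Bayesian Dirichlet-multinomial model of fungus-host
    association with normalized deviation statistics (posterior D-bar draws,
    their means and credible intervals, and the per-fungus maximum over
    hosts), rarefaction of sample-by-OTU count tables, plant-by-fungus
    association matrices at nested host clustering levels, OTU accumulation
    curves, Raup-Crick null-model beta-diversity, Mantel and partial Mantel
    permutation tests, Moran's I spatial autocorrelation, taxon frequency
    tables with Fisher-Holm contrasts, and a synthetic-data generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
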