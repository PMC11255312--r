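Package: halotrait
Title: Eco-Evolutionary Trait Analysis of Microbial Communities Along Salinity Gradients
Version: 0.1.0
Authors@R:
    person("halotrait", "developers", email = "halotrait@example.org", role = c("aut", "cre"))
Description: Tools to classify soil bacteria and archaea by their abundance
    response to an electrical-conductivity (salinity) gradient, detect
    breakpoints in group abundance trends by segmented least squares,
    normalize per-taxon functional-gene (KEGG orthology and CAZyme) content
    by taxon abundance, score completeness of salt-resistance and
    carbon-acquisition mechanism sets, run group contrasts (Mann-Whitney U,
    genome-size comparisons, partial correlation controlling salinity) and
    biomarker-pathway selection (difference-threshold rule and random-forest
    importance with cross-validated biomarker counts).  Ships a synthetic
    gradient-dataset generator with planted ground truth so every stage is
    testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
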