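Package: regnetsyn
Title: Drug Combination Synergy from Signed Directed Regulatory Networks
Version: 0.1.0
Authors@R: person("regnetsyn", "developers", role = c("aut", "cre"),
    email = "regnetsyn@example.org")
Description: Builds signed directed drug-target regulatory networks from KEGG
    KGML pathway files and tabular drug-target tables, propagates drug effects
    through the network with per-hop attenuation and negative-regulation
    blocking to weight every node by its intensity of action, partitions
    targets into positive and negative effect sets, and scores drug pairs by
    relative network distances between those sets to call combinations
    synergistic or antagonistic. Includes a differential-evolution and
    grid-search fitter for the attenuation coefficients, accuracy and ROC-AUC
    evaluation, a synthetic benchmark generator with planted synergy or
    antagonism structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
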