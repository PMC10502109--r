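Package: decoupleFBA
Title: Topology-Decoupled Constraint-Based Metabolic Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models in
    which topologically coupled reaction substructures (dense simple-cycle
    communities of the bipartite metabolite-reaction graph) are identified by
    weighted-cut clustering, replaced by sparse null-space basis vectors
    ("linear basis reactions"), and solved with reformulated flux balance
    analysis (FBA), parsimonious FBA, and flux variability analysis. Also
    provides a log-linear transcription-regulation model linking gene
    expression to biomass-constituent metabolite concentrations via partial
    least squares regression, and a linearized reversible Michaelis-Menten
    kinetic regression whose predicted fluxes can constrain the decoupled
    model. Includes readers and writers for COBRA JSON and SBML L3 FBC
    models, a synthetic-data generator with planted coupled-cycle structure
    and generative multi-omics tables, and evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mixOmics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
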