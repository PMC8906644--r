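Package: soilage
Title: Bacterial Age and Generation-Time Distributions in Soil Pore Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of an obligate-aerobic bacterial
    population colonizing a nutrient hotspot in an angular soil pore network
    under prescribed hydration (matric potential), together with the
    demographic post-processing that turns division-event logs into
    generation-time distributions, lineage dominance classifications and
    cell-age distributions.  Includes quasi-steady nutrient transport on the
    pore graph (carbon and oxygen with Henry-law gas/aqueous partitioning),
    run-and-tumble chemotaxis with film-thickness-limited motility,
    maximum-likelihood fitting of heavy-tailed generation-time distributions
    (power law, exponentially truncated power law, exponential, gamma,
    lognormal), and a heuristic steady-state cell-age model with
    gamma-distributed generation times, its degenerate (CV to 0) limit and
    community mixtures over lognormally weighted growth rates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
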