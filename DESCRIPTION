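Package: nitrocrust
Title: Nitrification Energetics, Nitrate Transport, and Archaeal Community
    Analysis for the Oxic Subseafloor Crust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for inferring in situ nitrification by
    ammonia-oxidizing archaea in oxic subseafloor basaltic aquifers. Computes
    Gibbs free energy of complete nitrification under in situ conditions and
    over concentration grids; estimates diffusive nitrate fluxes from porewater
    profiles by Fick's first law and runs a two-borehole reaction-transport box
    model yielding no-reaction endpoint concentrations, net nitrate reaction
    rates, and the nitrification share of oxygen consumption; fits qPCR
    standard curves and converts marker-gene copy numbers to cell densities in
    rock pore space and seawater; provides clone-library diversity statistics
    (p-distances, furthest-neighbor OTU clustering, bias-corrected Chao1,
    coverage, rarefaction) and community-table aggregation into clade profiles
    and heatmap tables. A seeded synthetic-data generator emulates the
    statistical structure of each input so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
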