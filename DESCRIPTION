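Package: phylorealms
Title: Phylogenetic Biogeographic Regionalization of Gridded Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to delimit nested biogeographic regions (phyloregions and
    realms) from gridded presence/absence communities and a phylogeny.
    Implements Simpson (turnover-only) species and phylogenetic beta
    diversity, linkage selection by cophenetic correlation, elbow-based
    choice of the number of regions, variance-threshold realm cuts, per-region
    diversity and endemism summaries (species richness, Faith's PD, weighted
    and phylogenetic endemism, evolutionary distinctiveness) and NMDS
    ordination of regions. Regionalization schemes can be compared with
    entropy-based V-measures against random Voronoi null schemes, and with
    boundary-distance correlations tested by an autocorrelation-corrected
    modified t-test. Environmental drivers of region boundaries are modelled
    with a spatial binomial mixed model fitted by penalized quasi-likelihood,
    and indicator clades are screened with geographic node divergence (GND)
    and per-cell specific overrepresentation scores (SOS). A synthetic-data
    generator with planted regional structure makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
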