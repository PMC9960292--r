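Package: mbopls
Title: Consensus Multiblock OPLS for Bioactivity-Guided Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links untargeted LC-MS metabolite profiles acquired in two
    ionization modes to an enzyme-inhibition response through a consensus
    (multiblock) orthogonal projections to latent structures (OPLS) model.
    Provides plate-level computation of alpha-glucosidase inhibition
    percentages and IC50 values, feature-table filtering (retention-time
    window, intensity threshold, correlation pruning of co-eluting ions),
    a kernel-based consensus OPLS with cross-validated Q2 and permutation
    testing, loading-based selection of bioactivity-associated ions,
    nonparametric group comparisons with compact letter displays, and a
    synthetic-data generator emulating a 9-tree x 3-organ x 2-site plant
    extract study so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
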