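Package: tcrdyn
Title: Multidimensional Analysis of T-Cell Receptor Beta Repertoire Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal, multi-subpopulation analysis of T-cell
    receptor beta (TCRbeta) clonotype repertoires. Reads AIRR-style clone
    tables, computes Hill-number diversity and q-parameterized clonal
    expansion (Shannon evenness) profiles, quantifies clonal persistence
    between timepoints, classifies public and private clones, builds
    Levenshtein-distance-1 CDR3 similarity networks with degree and
    connectivity statistics, derives CDR3 k-mer decomposition profiles, and
    annotates repertoires against curated CDR3 databases (McPAS-TCR and
    VDJdb export layouts). A seeded synthetic cohort generator emulates a
    two-arm, two-timepoint sorted-subpopulation study design with tunable
    clone-frequency polarization, cross-timepoint persistence, and shared
    public-clone pools, so that every pipeline stage can be exercised and
    validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
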