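Package: mrforge
Title: Search-Model Factories for Molecular Replacement from a Single Distant Homologue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns one crystal structure of a distant homologue into pools of
    molecular-replacement search models. A constraint-based distance-geometry
    generator expands the single structure into a conformational ensemble;
    ensemble members are clustered, per-residue structural variance is
    estimated by iteratively reweighted superposition, and graded truncation
    combined with subclustering radii and side-chain treatments yields the
    search-model pool. A second, single-structure mode truncates one model
    progressively according to per-residue score profiles (external score
    files or built-in packing and rigidity metrics: weighted contact number,
    solvent-accessible surface area, residue-averaged B factors, ensemble
    variance). Outputs are PDB files (single-model or multi-MODEL ensembles)
    plus a manifest. No diffraction data is consumed and no molecular
    replacement program is run.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'structure-io.R'
    'fixtures.R'
    'secondary.R'
    'constraints.R'
    'dg-ensemble.R'
    'superpose.R'
    'cluster.R'
    'variance.R'
    'truncation.R'
    'score-mode.R'
    'metrics.R'
    'pipeline.R'
    'zzz.R'
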