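Package: vecgen
Title: Vector-Driven Connectivity and Microsatellite Population Genetics of
    Marine Invasions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether directional transport-vector networks
    (e.g. commercial vessel traffic between ports) predict population-genetic
    connectivity among established populations of an invasive species.
    Implements descriptive microsatellite statistics (allelic richness by
    hypergeometric rarefaction, unbiased gene diversity, Weir-Cockerham
    fixation indices and pairwise theta), a no-admixture Gibbs sampler for
    Bayesian clustering with Evanno delta-K model choice, Rannala-Mountain
    genotype assignment and assignment-based directional migration matrices,
    Cornuet-Luikart heterozygosity-excess bottleneck tests under a two-phase
    mutation model, and rank-based Mantel permutation tests that admit
    asymmetric matrices. A forward-time Wright-Fisher simulator with
    vector-proportional directional migration, partial selfing and two-phase
    microsatellite mutation generates study-scale synthetic genotype panels
    for calibration and power analysis. GENEPOP genotype files and labeled
    delimited matrices are read and written natively.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'assign.R'
    'bottleneck.R'
    'cluster.R'
    'genepop-io.R'
    'mantel.R'
    'pipeline.R'
    'popgen.R'
    'synthio.R'
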