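Package: RadPopGen
Title: Population Genomics of RAD-Seq SNP Panels: Filtering, Structure,
    Introduction Tracing and Selection Scans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of diploid biallelic SNP
    genotypes from reduced-representation (RAD/GBS) sequencing, organised
    around a GenotypeData container extending RangedSummarizedExperiment.
    Implements the SNP quality-filter cascade used for RAD genotype panels
    (per-population call rate, paralogous-tag removal, one SNP per tag,
    exact Hardy-Weinberg tests, minor-allele-frequency, missingness and
    linkage-disequilibrium pruning); per-population diversity statistics,
    Weir-Cockerham F(ST) with permutation tests, isolation-by-distance
    Mantel tests, Nei's standard genetic distance with neighbour-joining
    trees, and genotype PCA; maximum-likelihood admixture estimation with
    cross-validation over the number of clusters; approximate Bayesian
    computation for choosing among demographic scenarios of population
    introduction (coalescent scenario simulator, summary-statistic
    reference tables, logistic-regression model choice, type I/II error
    estimation, parameter posteriors and PCA model checking); three
    complementary selection scans (environmental-association Bayes factors
    with an allele-frequency covariance null, hierarchical island-model
    F(ST) outlier tests, and a Bayesian F-model with reversible-jump MCMC);
    and sliding-window F(ST) scans with genomic-island detection. A
    synthetic-data generator reproduces the statistical structure of a
    multi-river-system sampling design with admixed and bottlenecked
    introduced populations, so every stage can be exercised and calibrated
    without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    vcfR,
    geosphere,
    jsonlite,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics
RoxygenNote: 7.3.3
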