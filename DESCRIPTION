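Package: genedensity
Title: Gene-Number and Genome-Size Distributions Across Sequenced Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Histogram-based density estimation of gene counts and genome
    sizes over large collections of sequenced genomes, and mechanistic models
    of both: a mixture of a uniform background, five shifted Poisson
    components and a step input with exponential decay (the bg5Ps model) for
    the gene-number density, and a logistic-type ordinary differential
    equation with closed-form solution for the dependence of genome size on
    gene number. Includes bounded nonlinear least-squares fitting with
    staged component addition and hold-out validation, estimation of
    cumulative extensive and intensive gene fractions, comparison with
    empirical protein-coding, pseudogene and non-coding fractions, a
    synthetic genome-table generator for simulation studies, and readers for
    NCBI 'datasets' genome summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
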