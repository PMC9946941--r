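Package: scCloneTree
Title: Clonal Tree Reconstruction by Integrating Bulk DNA-Seq and Single-Cell RNA-Seq Variant Read Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian reconstruction of cancer clonal trees from bulk DNA
    sequencing variant read counts (with clonal major/minor copy numbers)
    integrated with sparse single-cell RNA sequencing variant read counts.
    The model places a tree-structured stick-breaking (TSSB) prior on the
    clonal tree and the SNV-to-clone assignment, a genotype-marginalized
    binomial likelihood on bulk variant allele counts, and a Beta-Binomial
    mixture (mono-/bi-allelic bursty expression) on single-cell allelic
    counts with the cell-to-clone membership marginalized out. Inference is
    by MCMC (slice sampling of SNV assignments, conjugate Gibbs updates of
    the sticks, Metropolis-Hastings on clone fractions), yielding posterior
    samples and a MAP tree, cellular prevalences, and posterior
    cell-to-clone assignments. A matched generative simulator, SNV
    filtering and per-locus allelic-imbalance estimation, and evaluation
    metrics (V-measure, adjusted Rand index, adjusted mutual information,
    ancestral reconstruction error, expected per-cell genotype loss) are
    included, along with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR
Config/testthat/edition: 3
biocViews: Software, Bayesian, Phylogenetics, SingleCell, Transcriptomics, SomaticMutation
RoxygenNote: 7.3.3
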