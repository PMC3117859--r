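Package: mirstem
Title: Small RNA-Seq miRNA Profiling, Novel miRNA Discovery and
    Target-Network Analysis for Embryonic Stem Cells
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end small RNA sequencing analysis toolkit modelled on
    multiplexed Solexa-era miRNA profiling of primate embryonic stem cell
    lines. Provides a synthetic-data generator with planted ground truth
    (genomes, hairpin precursor loci, indexed 35 nt libraries, target tables
    with a tunable degree-versus-dN/dS relation, cross-species profiles);
    read preprocessing (demultiplexing, 3' adapter trimming, length/quality
    filtering, tag collapsing); exact genome mapping with hierarchical
    category annotation and known-miRNA quantification; novel miRNA
    discovery from unannotated tags via a stacking-aware hairpin folding
    dynamic program with structural and energy criteria; expression
    consistency statistics over miRNA clusters (Poisson background
    thresholds, entropy-based divergence, coefficient of variation,
    differential index, Cohen's kappa with Z-score); seed-match target
    prediction, bipartite miRNA-target network construction with a
    preferential-attachment null model and degree-versus-evolutionary-rate
    correlation; and cross-species expression comparison with hierarchical
    clustering and named-cluster contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, GeneRegulation, NetworkInference, Software
RoxygenNote: 7.3.3
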