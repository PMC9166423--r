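Package: cprlib
Title: Ecogenomics of Candidate Phyla Radiation Metagenome-Assembled Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream ecogenomic analysis of candidate phyla radiation (CPR,
    Patescibacteria) metagenome-assembled genomes from freshwater lakes.
    Provides taxonomy-vote and viral-fraction contig decontamination,
    completeness/contamination estimation from a 43 single-copy marker gene
    set with a strict quality gate, single-linkage dereplication of genomes
    at an average nucleotide identity threshold with scored representative
    selection, fragment-recruitment abundance estimation normalized as
    coverage per gigabase of metagenome, a replication-skew (ori/ter) index
    from window coverages, classification of microbial rhodopsins into Type I
    ion pumps and heliorhodopsins from hydropathy-derived membrane topology
    and the transmembrane-helix-7 retinal-binding motif, and genome
    streamlining trait statistics across lifestyle categories. A synthetic
    data module generates every input with planted ground truth so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, QualityControl, Clustering, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bin.R'
    'config.R'
    'cprlib-package.R'
    'derep.R'
    'io.R'
    'qc.R'
    'recruit.R'
    'rhodopsin.R'
    'simulate.R'
    'traits.R'
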