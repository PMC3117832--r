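Package: evoplast
Title: Evolutionary Plasticity of Orthologous Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how plastic or conserved a gene family has been
    across eukaryotic evolution from its phyletic pattern alone. For each
    orthologous group (KOG/COG-style) the package computes the normalized
    Shannon diversity of member counts across a species panel, the
    abundance (average copies per occupied species), and combines them
    into the Evolutionary Plasticity Index (EPI). Downstream layers
    compute Poisson-corrected amino-acid distances with pairwise deletion
    from per-group alignments, correlate distance with EPI, compare EPI
    distributions of phenotype-labeled gene sets (e.g. essential versus
    viable knockouts), and project EPI onto protein-interaction networks
    with neighborhood smoothing. A seeded gene-family simulator generates
    membership tables and diverged alignments so the whole pipeline is
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Phylogenetics, ComparativeGenomics, Network, Software
RoxygenNote: 7.3.3
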