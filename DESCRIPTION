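Package: pdzscreen
Title: Protein Microarray Hit Calling, GO Similarity Clustering and PDZ
    Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for turning duplicate-spot protein
    microarray fluorescence into a clustered, motif-annotated PDZ-domain
    interactome. Implements background correction, LOWESS de-trending,
    concentration adjustment and Z-score/CV duplicate-spot hit calling
    with replicate-slide intersection; interactor-list assembly with
    provenance merging, annotation-status filtering and domain-category
    enrichment; Gene Ontology annotation clustering via simUI graph
    similarity, partitioning around medoids and silhouette-based
    selection of the number of clusters, with thresholded network
    export; and classification of C-terminal sequences into PDZ-binding
    motif classes, including terminal-cysteine ligands and the binding
    site identity transfer rule. Synthetic-data generators for array
    slides, ontologies with group-structured annotations and C-terminal
    peptide sets support end-to-end validation with planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
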