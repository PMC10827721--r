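Package: trichonet
Title: Gene Co-Expression Network Analysis of Plant-Trichoderma Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing bulk RNA-seq count data
    from plant-microbe interaction experiments: trimmed-mean-of-M-values
    normalization, negative-binomial likelihood-ratio differential expression
    with FDR and fold-change filters, significance-filtered Spearman gene
    co-expression networks, random-walk (walktrap) community detection with a
    modularity-optimal cut, composite hub-gene scoring
    (degree x closeness x authority), targeted node-removal robustness
    analysis, control-versus-stimulus differential network comparison, and
    hypergeometric term-overrepresentation statistics. Includes a synthetic
    count-data generator with planted differentially expressed genes,
    co-expression modules, and hub genes so the whole chain is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    jsonlite,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust
Config/testthat/edition: 3
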