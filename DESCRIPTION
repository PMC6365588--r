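Package: arcseq
Title: Simulation, Quantification and Multimodal Analysis of Antibody
    RNA-Barcode Conjugate Single-Cell Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for plate-based single-cell libraries that carry both
    endogenous transcripts and antibody RNA-barcode conjugates (ARCs) in
    read 1 with the cell barcode and UMI in read 2. Includes a ground-truth
    library simulator, anchor-based ARC detection with mismatch tolerance,
    UMI-collapsed quantification into matched mRNA and antibody count
    tables, depth normalization by random subsampling without replacement,
    and the downstream multimodal analysis: log normalization, variable
    gene selection, PCA/t-SNE embedding, antibody count ratios, gene
    signature scores, extreme-cell selection, group resampling and
    differential expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    matrixStats,
    Rtsne,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
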