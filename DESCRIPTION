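Package: coevnet
Title: Co-Evolving Residue Networks in Protein Super-Family Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects networks of co-evolving residue positions in large
    protein super-family multiple sequence alignments. Pairwise correlated
    mutation scores are computed with a perturbation-based statistical
    coupling analysis or with normalized mutual information, thresholded
    into weighted position networks, and annotated with literature-derived
    mutation data mined from article text. Keyword enrichment scores with
    permutation p-values quantify the functional signal carried by a
    network, sub-alignment and random-subsampling scans probe network
    robustness, and degenerate-codon sets are designed to randomize network
    positions in small combinatorial mutant libraries. A synthetic
    super-family generator with planted co-evolving position sets and a
    synthetic mutation-sentence corpus provides a fully controlled test
    bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
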