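Package: coexclade
Title: Gene Coexpression Trees and Driver-Gene Clade Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome-wide coexpression trees from bulk expression
    matrices by UPGMA clustering of Pearson-correlation distances
    (d = 1 - r), selects representative samples by iterative pruning of
    adjacent tree leaves, extracts and resizes the coexpression clade
    around a user-chosen driver gene, and tests clade gene lists for
    biological-term enrichment with the hypergeometric distribution and
    Benjamini-Hochberg false-discovery-rate control. Includes tissue-aware
    smoothed quantile normalization for count matrices, Newick and PHYLIP
    distance-matrix input/output, a sliding clade scan for locating gene
    families on the tree, and synthetic-data generators with planted
    coexpression modules for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
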