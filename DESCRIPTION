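Package: spcount
Title: Label-Free Spectral Counting for Two-Condition Differential Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a label-free, spectral-count based semiquantitative
    proteomics pipeline for comparing two conditions: aggregation of
    peptide-spectrum matches into protein-level count matrices, the
    pseudo-count corrected log2 spectral-count ratio (Rsc) with a fixed
    fold-change selection rule, normalized spectral abundance factors
    (NSAF), Venn-style comparison of identification sets, local
    hypergeometric category enrichment, and corneal wound-healing
    percentages. Ships a multinomial spectral-count simulator with planted
    fold changes for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
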