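Package: shellform
Title: Multi-Organ Origin Classification and Shell-Damage Recurrence
    Analysis for Shell Matrix Protein Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating the organ of origin of mollusk shell matrix
    protein (SMP) genes from a multi-organ RPKM expression atlas, and for
    identifying shell-formation-related genes as those persistently
    upregulated across a shell-damage time course without biological
    replicates.  Differential expression between single libraries uses the
    Audic-Claverie exact conditional test; persistence is judged by counting
    the sampling dates on which a gene is called upregulated and comparing
    the resulting recurrence histogram to a random-recurrence null
    (Poisson-binomial closed form or date-wise permutation).  Includes
    hypergeometric term enrichment with Benjamini-Hochberg adjustment, a
    negative-binomial count simulator with known ground truth for
    end-to-end validation, and TSV-based input/output for count matrices,
    sample manifests and annotation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
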