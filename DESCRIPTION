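Package: wolbmeta
Title: Cross-Study Meta-Analysis of Wolbachia Effects on Aedes aegypti
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes and gene sets consistently affected by
    Wolbachia infection across independent Aedes aegypti transcriptomic
    contrasts. Combines per-contrast differential-expression p-values under
    the conjunction null with the maxP statistic, runs pre-ranked gene set
    enrichment with a permutation null, controls the false discovery rate
    with the Benjamini-Hochberg procedure, and calls consistently up- or
    downregulated traits using directional-consistency criteria. Includes a
    multi-study simulator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
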