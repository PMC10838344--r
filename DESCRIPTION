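Package: flipmoa
Title: Flip-Signature Mode-of-Action Analysis for Perturbation-Drug
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genes whose perturbation-induced dysregulation is
    reversed ("flipped") by a candidate drug, from a three-condition bulk
    RNA-seq design (control, perturbed, perturbed plus drug). Provides a
    transparent negative-binomial Wald differential-expression test with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    flip-signature classification, enrichment-factor pathway scoring with
    hypergeometric significance, a pathway overlap network grouped by
    K-means, preranked regulon enrichment with permutation-normalized
    enrichment scores, and a connectivity-map style screen that ranks drug
    expression profiles by Jaccard similarity to the flip signature and
    scores enriched drug targets. A seeded synthetic-data generator with a
    ground-truth manifest produces every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    cluster,
    igraph,
    jsonlite
Suggests:
    fgsea,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
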