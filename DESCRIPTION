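Package: clonedriver
Title: Clonality-Aware Bayesian Discovery of Cancer Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies positively selected cancer driver genes from cohort
    somatic-mutation data by combining population recurrence, cancer cell
    fraction (CCF) and functional impact. Per-mutation CCF is estimated from
    variant allele frequency, tumor purity and local copy number; raw
    CADD-like impact scores are mapped to damage probabilities by a logistic
    transform. A per-gene background mutation probability is obtained by
    averaging a CCF-adjusted Ka/Ks (dN/dS) model with a non-coding
    mutation-rate model, and two Bayesian models (a cancer-hazard model and a
    driver-inference model) turn the per-gene evidence mass into posterior
    probabilities. A gene-label resampling null model estimates the false
    discovery rate at each rank and suggests a significance cutoff. Includes
    a synthetic-cohort simulator with known driver/passenger ground truth and
    benchmarking utilities (precision/recall/F-score curves, truncated Borda
    count rank aggregation, Fisher enrichment tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
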