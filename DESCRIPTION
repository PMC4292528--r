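Package: famrare
Title: Family-Based Designs and Score Tests for Rare-Variant Disease Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for rare-variant disease
    association with family-based designs. Implements five transmission-based
    score tests (UminP, score, SSU, SSUw, sum) computed from minor-allele
    transmissions of heterozygous parents to affected offspring, the
    multiple-test-corrected single-SNP TDT, and a case-control battery
    (single-SNP association, C-alpha with analytic and permutation p-values,
    SKAT with Beta-density minor-allele-frequency weights, and KBAC with a
    cumulative hypergeometric kernel). Family data (parent-child trios,
    affected sib-pairs, and enriched trios) can be transformed into
    pseudo-case-control data built from untransmitted parental alleles or
    combined with unrelated population controls, with a clustering step that
    restores independence when families contribute several affected siblings.
    An exact tilted sampler generates families ascertained on offspring
    affection under a logistic penetrance model, enabling power and type-I
    error estimation by replication at realistic disease prevalences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    mvtnorm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
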