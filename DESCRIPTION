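Package: pepqsar
Title: Peptide QSAR Descriptors, PLS-DA Cell-Penetration Classification
    and Infusion Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative structure-activity modeling of
    cell-penetrating peptides (CPPs).  Builds three-component amino-acid
    z-scales by principal component analysis of physicochemical property
    tables and ships a published 20-residue scale as reference data;
    computes global peptide descriptors on that scale (mean z-scores,
    helical-wheel z-scale moments, terminal differences, steric bulk,
    hydrogen-bond balance, charge composition and hydrophilic ratio);
    assembles labeled peptide corpora with deduplication, class balancing,
    terminal truncation and train/test splitting; fits and cross-validates
    NIPALS PLS-DA classifiers with sensitivity, specificity, accuracy and
    Matthews correlation reporting; and simulates one-compartment
    intravenous-infusion pharmacokinetics with closed-form AUC and Cmax.
    A seeded generator of synthetic cationic/amphipathic peptide corpora
    makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    mixOmics,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
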