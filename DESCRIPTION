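Package: taqase
Title: Allele-Specific Expression from Dual-Probe TaqMan Amplification Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allele-specific expression (ASE) from raw dual-channel
    (FAM/VIC) TaqMan real-time PCR fluorescence. Amplification curves are fitted
    with a four-parameter sigmoid using a plateau-robust two-step refinement;
    each reaction is summarised by the transformed fluorescence ratio k', a
    branch-conditional statistic built from the fitted plateau heights and
    inflection cycles of the two channels. k' is calibrated against plasmid
    mixtures of known allele composition via an ordinary least-squares standard
    curve and inverted to per-sample allele-frequency estimates, which are then
    compared across tissues (one-sample tests against a balanced 1:1 ratio,
    one-way ANOVA with Tukey post-hoc contrasts). Companion tools compare
    promoter alleles (Needleman-Wunsch alignment, SNP/indel detection) and
    predict CpG islands by the sliding-window GC / observed-to-expected CpG
    criteria. A seeded simulator generates dual-channel amplification plates and
    promoter sequence pairs with planted features for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
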