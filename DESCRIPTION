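Package: phasereg
Title: Phase-Aware Association Testing for Pairs of Genetic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests whether the cis or trans phase configuration of two
    genetic variants is associated with a phenotype, using an additive
    "phasetype" coding of phased two-locus diplotypes inside a generalized
    linear model that adjusts for each variant's additive and dominance
    main effects.  Includes the multi-allelic extension for haplotype
    blocks, benchmark epistasis tests (1-df and 4-df genotype interaction,
    the saturated model with a phase indicator, the haplotype odds-ratio
    test, haplotype regression), readers for phased VCF input, and a
    simulation framework for type-I-error, power, linkage-disequilibrium
    sensitivity and switch-error robustness studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, vcfR, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
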