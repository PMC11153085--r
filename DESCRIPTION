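Package: holobiome
Title: Joint Bacterial and Yeast Microbiome Analysis Under Salinity Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the joint bacterial and yeast microbiome of
    host lines adapted to substrates of increasing NaCl concentration:
    preparation of genus-level relative-abundance tables (replicate
    averaging, endosymbiont exclusion, rare-taxon lumping), Shannon
    diversity, a biocenotic similarity coefficient combining shared-species
    and shared-abundance components, colony-forming-unit quantification
    from serial dilution plating, NaCl growth-tolerance statistics
    (two-way ANOVA and Tukey HSD), a tie-aware Spearman/Kendall pairwise
    correlation screen with sample-exclusion sensitivity, and a
    seed-deterministic synthetic-study generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
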