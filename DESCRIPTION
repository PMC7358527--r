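Package: soilvir
Title: Soil Viral Ecology Pipelines: Prophage Induction, Fingerprinting and
    Ordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines for seasonal soil viral-ecology field studies.
    Quantifies mitomycin-C prophage-induction assays (burst size, inducible
    fraction under calculated and assumed burst-size conventions, percent
    increase in viral abundance), processes replicate T-RFLP electropherogram
    peak tables into consensus, normalized, binned community matrices with
    Shannon diversity, analyses genetic-fingerprint band patterns (Dice
    similarity, UPGMA dendrograms, nonmetric multidimensional scaling), and
    provides the study-level statistics layer (Spearman rank correlations,
    repeated-measures ANOVA with Tukey post-hoc, canonical correspondence
    analysis with a Monte Carlo permutation test). Includes a seeded
    synthetic-study generator emulating a five-treatment, six-month,
    triplicate-plot design with ground truth retained for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
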