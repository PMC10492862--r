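Package: acstoich
Title: Lysine Acetylation Stoichiometry from Paired Light/Heavy Acetyl Fragment Ions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies site-level lysine acetylation stoichiometry from
    fragment-ion peak areas of endogenous (light acetyl) and chemically
    labeled (D3-acetyl) peptide species, as produced by data-independent
    acquisition workflows after complete chemical acetylation with
    D6-acetic anhydride. Provides in-silico Trypsin/GluC digestion with
    acetyl-blocked lysines, b/y fragment-ion pair generation, isotope
    envelope computation with natural-isotope envelope correction of the
    heavy channel, per-site group comparison via one-way ANOVA with
    Fisher-combined p-values, model-overlap summaries, category
    over-representation analysis, and a ground-truthed synthetic-data
    generator for benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
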