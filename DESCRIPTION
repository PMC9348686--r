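Package: sociodom
Title: Social Dominance Hierarchies from Electronic Feed Bin Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects competitive replacements at electronic feed or water
    bins from individual visit logs and derives the social dominance
    structure of a group of animals: actor/reactor interaction lists,
    sociomatrix and dyadic dominance matrix, Kondo-Hurnik dominance values
    with social rank and hierarchy categories, Landau's linearity index and
    de Vries's improved index, comparison indices (David's score, Elo
    rating) with cross-method Pearson correlations, and bar, box and
    sociogram visualisations. Includes a synthetic-data generator with a
    known latent hierarchy so every stage of the pipeline can be validated
    without field data, and a command-line interface chaining the full
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
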