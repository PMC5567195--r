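Package: habstatus
Title: Habitat Conservation Status Assessment and Citizen-Science Data Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Plot-level conservation-status assessment of Natura 2000 habitat
    types from field protocols (specific structures and functions, typical
    species, pressures and threats), classified to the Habitats Directive
    Article 17 classes Favourable (FV), Unfavourable-Inadequate (U1) and
    Unfavourable-Bad (U2). Includes tools to compare surveys made by expert
    and non-expert (citizen-science) observers: per-plot richness,
    completeness and accuracy metrics, cumulative pooling of records with
    low-support outlier flagging, habitat-patch edge-distance analysis of
    plot placement, and permutational ANOVA (one-way and two-way main
    effects) for inference on per-plot counts. A synthetic survey generator
    with observer-specific detection probabilities, seasonal herb
    detectability, false positives and edge-biased plot placement makes the
    whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
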