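Package: introqtl
Title: Substitution Mapping of Volatile Metabolite QTLs in Near-Isogenic
    Line Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTLs) of fruit
    volatile organic compounds (VOCs) in panels of near-isogenic lines
    (NILs) carrying overlapping donor introgressions. Implements the full
    analysis chain for an introgression panel on melon chromosome 3:
    relative-abundance normalisation with detection-limit zero
    substitution and log2 transformation; per-trait ANOVA screening with
    Benjamini-Hochberg correction and Dunnett many-to-one comparisons
    against the recurrent parent; a substitution-mapping engine that
    converts per-line significance patterns and marker-resolved
    introgression extents into single-QTL intervals, with classification
    of each QTL as colocalizing or not with the climacteric-ripening
    region ETHQB3.5 (ethylene-dependent vs -independent); thresholded
    Pearson correlation networks and Ward hierarchical clustering of the
    trait panel; and a replicate-level simulator with planted QTL
    effects, latent correlation blocks and detection-limit censoring for
    end-to-end validation. Ships transcribed marker, trait-pattern and
    QTL tables from the source study as plain-text fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
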