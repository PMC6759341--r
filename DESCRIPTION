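Package: mycnest
Title: Nestedness and Disturbance-Tolerance Analysis of Paired AM Fungal
    Communities
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing arbuscular mycorrhizal (AM) fungal OTU
    tables from paired intact/disturbed trap cultures sampled along an
    environmental (elevation) gradient. Provides OTU-table input/output
    (TSV and BIOM-style JSON), read-depth standardization by rarefaction,
    richness and Shannon-Wiener diversity, Bray-Curtis dissimilarity,
    permutation inference (Mantel test, one-way PERMANOVA), Tukey HSD
    compact letter displays, NODF nestedness with a column-total-fixed
    Monte-Carlo null model and z-scores, per-OTU disturbance
    responsiveness/robustness/occurrence indices, a synthetic paired
    community generator with planted nestedness and tolerance structure,
    and a command-line pipeline that orchestrates the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
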