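Package: tmtbridge
Title: Pooled-Reference Quantification and Power-Gated Differential
    Analysis for Multiplexed TMT Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for isobaric tandem-mass-tag (TMT) proteome
    experiments that span several labeling sets (plexes) bridged by pooled
    internal-reference channels. Converts protein-level reporter-ion
    intensities to relative abundances against the pooled reference, merges
    plexes into a commonly-detected protein matrix, monitors reproducibility
    through pooled-channel coefficients of variation, and scores differential
    expression per treatment with Student t-tests, post-hoc power gating and
    fold-change filters. Includes a pathway dysregulation statistic that
    contrasts the percentage of significantly changed pathway members against
    the pathway's detection coverage, right-tailed Fisher (hypergeometric)
    enrichment with a selectable background universe, a mitochondrial
    functional-class breakdown, and a ground-truthed synthetic-data generator
    emulating a two-plex, six-group cardiomyocyte toxicant study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
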