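Package: brgdgt
Title: Branched GDGT Lipid Proxies for Benthic Oxygen Uptake
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with branched glycerol dialkyl glycerol
    tetraether (brGDGT) membrane lipids as proxies of benthic
    biogeochemistry. Reads HPLC-APCI-MS selected-ion-monitoring peak
    tables, quantifies compounds against a C46-GTGT internal standard,
    computes fractional abundances and the standard proxy index suite
    (IMBT, BIT, Sigma-IIIa/Sigma-IIa, IR, MBT'5ME, CBT5ME, ternary
    coordinates), fits and applies the log-linear IMBT to diffusive
    oxygen uptake (DOU) transfer function with uncertainty and inverse
    sensitivity analysis, classifies brGDGT sources (soil vs. marine),
    and provides compositional statistics (Bray-Curtis dissimilarity,
    principal coordinates analysis, Pearson correlation maps, one-way
    ANOVA) plus a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
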