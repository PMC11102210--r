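Package: cmuQuant
Title: Spike-In Calibrated Absolute Quantification of Shotgun Oral
    Microbiome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts shotgun-metagenomic relative abundances of dental
    plaque communities into absolute per-species cell counts (calculated
    microbial units, CMUs) using per-sample spike-in calibration curves
    and genome molecular weights. Provides clinical-category aggregation
    of oral taxa (commensal, gingivitis, malodor, acidogenic), alpha
    diversity, weighted UniFrac distances with PCoA ordination and
    PERMANOVA, two-group contrasts with percent-reduction summaries, the
    noncentral-t power computation used for two-arm trial sizing, and a
    synthetic five-arm study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phyloseq,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
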