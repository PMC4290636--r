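Package: phosmine
Title: Alkaline-Phosphatase-Assisted Phosphopeptide Signal Mining for
    Targeted LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines candidate phosphopeptide signals from paired (untreated
    versus alkaline-phosphatase-treated) LC-MS peak lists by detecting
    neutral-mass shifts of multiples of the phosphate-group mass (79.966 Da),
    builds retention-time-windowed m/z inclusion lists for targeted LC-MS/MS
    acquisition, and links search-engine phosphopeptide identifications to
    pattern-based label-free quantification features, including Mascot
    delta-score site-localization summaries and per-feature ANOVA tests of
    differential abundance. Includes a deterministic synthetic-data generator
    with planted ground truth for end-to-end validation, and a command-line
    interface over all pipeline stages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
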