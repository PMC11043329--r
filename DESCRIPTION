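Package: mnasequant
Title: Quantitative MNase-Seq Analysis of Promoter Nucleosome Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying nucleosome repositioning from MNase-seq
    data in TSS-anchored promoter windows. Converts size-selected paired-end
    fragments to 1-bp fragment-center coverage, normalises per-promoter
    profiles, tests per-base-pair differential occupancy between two cell
    states with paired t-tests across a priori gene groups, calls and
    classifies repositioning regions (shift, build-up, loss), fits
    two-Lorentzian and constrained-spline models to difference profiles,
    correlates groups over called regions, and calls broad ChIP-seq binding
    sites with an input-subtracted 4-sigma rule. Includes a seeded synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
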