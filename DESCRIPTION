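Package: otowave
Title: Analysis of Spontaneous Activity in the Developing Auditory System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of spontaneous activity in the pre-hearing
    auditory system. Provides burst detection in spiral ganglion neuron spike
    trains via interspike-interval classification, spontaneous inward-current
    and holding-current statistics for voltage-clamp recordings, crenation and
    calcium-transient detection in cochlear image stacks, bilateral and
    tonotopic event analysis for widefield midbrain movies, retinal-wave
    detection in the superior colliculus, the accompanying statistical toolbox
    (D'Agostino K-squared normality test, Bonferroni-corrected comparisons,
    one-way ANOVA with Tukey post hoc, two-mean sample-size calculation), and a
    synthetic-data generator with ground-truth logs so every stage is testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    EBImage,
    tiff,
    data.table,
    jsonlite,
    minpack.lm,
    yaml,
    mgcv
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
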