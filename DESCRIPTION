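Package: beescape
Title: Pollinator Communities, Pollen Limitation and Pollination Economics
        for Highbush Blueberry Field Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: An analysis pipeline for two-region pollinator field studies in
        commercial highbush blueberry. Provides species-richness estimation
        (Chao-1, Shannon-Wiener, sample-based rarefaction with permutation
        envelopes), community-composition analysis (Bray-Curtis
        dissimilarity, non-metric multidimensional scaling, environmental
        vector fitting, PERMANOVA), negative-binomial mixed modelling of
        flower-visitor counts with AICc-based multimodel inference and full
        model averaging, pollination-treatment contrasts (pollinator
        exclusion, open pollination, hand supplementation) including
        pollinator-contribution and pollination-deficit estimation, and a
        crop-yield and farm-gate valuation model for the economic value of
        insect pollination. A synthetic-data generator with known ground
        truth emulates the full study design so every stage can be tested
        without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, vegan, glmmTMB, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
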