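Package: fos3nn
Title: Neutropenia Risk Stratification from First-Cycle Blood Counts via
    Fast Orthogonal Search and Nearest-Neighbour Classification
Version: 0.1.0
Authors@R:
    person("CCSEO", "Modelling Group", email = "fos3nn@example.org",
           role = c("aut", "cre"))
Description: Implements the FOS-3NN cascade for stratifying chemotherapy
    patients into high- and low-risk groups for neutropenic events using
    complete-blood-count (CBC) markers from the first treatment cycle.
    Fast Orthogonal Search (FOS) greedily selects, from the 12 first-cycle
    CBC markers and their 78 second-order cross-products, the terms that
    maximally reduce mean-squared error against a +/-1 risk outcome; the
    selected terms define the coordinate space of a 3-nearest-neighbour
    majority-vote classifier. Includes rule-based retrospective risk
    labelling from treatment-event records, exact 2x2 contingency
    statistics (Fisher's exact test, Matthews' correlation coefficient),
    two-sample t-tests for marker-wise group comparison, a synthetic
    cohort generator for end-to-end validation without clinical data, and
    a command-line interface wiring the stages into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
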