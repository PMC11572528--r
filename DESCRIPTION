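Package: resilgrey
Title: Grey Clustering and Attribute-Hierarchy Weighting for Emergency-Resilience Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying weighted multi-level evaluation
    scales of the kind used to assess the emergency resilience of grassroots
    medical workers. Implements Delphi-round concordance statistics (Kendall's
    W with tie correction) and indicator screening, Attribute Hierarchy Model
    (AHM) weighting of Saaty 1-9 pairwise comparison matrices with classical
    AHP eigenvector consistency diagnostics, grey fixed-weight clustering with
    whitening weight functions over four grey classes, grey relational scoring,
    questionnaire validity filtering, rank-based group comparisons, and a
    synthetic-data generator with known ground truth for expert panels, Delphi
    rounds and Likert respondent cohorts. Ships a published three-level
    resilience indicator scale (3 first-level, 13 second-level, 46 third-level
    indicators with weights) as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
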