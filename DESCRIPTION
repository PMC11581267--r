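Package: exanterank
Title: Ex-Ante Multi-Criteria Impact Assessment and TOPSIS Ranking of
    Agricultural Technologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ex-ante impact assessment of candidate agricultural research
    technologies along three outcome criteria: the benefit-cost ratio of
    research and dissemination investment derived from a closed-economy
    economic-surplus model with discounting, the change in the number of
    poor people obtained through a poverty elasticity of agricultural
    productivity, and the change in the number of malnourished children
    under five projected with a calorie-driven recursion. Region-specific
    criteria weights are derived from development indicator ratios
    (agricultural GDP share, poverty headcount, child stunting) and the
    technologies are ranked with the TOPSIS multi-criteria method.
    Includes a seeded synthetic-data generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
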