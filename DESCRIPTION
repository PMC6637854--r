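Package: fvgap
Title: Projecting Gaps Between Fruit and Vegetable Supply, Demand, and
    Recommended Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simplified partial-equilibrium multimarket simulator for
    projecting fruit and vegetable availability under alternative
    socioeconomic scenarios, together with population-pyramid-weighted
    WHO consumption targets, household food-waste scenario adjustment,
    gap and coverage summaries, and classification of food-policy records
    onto the Nuffield intervention ladder. Ships a seeded synthetic world
    generator so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
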