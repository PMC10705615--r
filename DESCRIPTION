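Package: fibrewelfare
Title: Animal Welfare Risk Assessment for Fibre-Producing Animals
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A risk assessment tool for the welfare of fibre-producing farm
    animals (sheep, goats, cattle, alpacas, waterfowl) under the Five Domains
    framework. Yes/no single-measure questionnaires about a textile standard's
    obligatory requirements are scored through decision trees into provision
    scores (0-100), aggregated per domain by a discrete Choquet integral with
    respect to an expert-elicited capacity (fuzzy measure), combined by a
    median into a final mental-state score, and mapped to one of five welfare
    risk categories. Ships the reference feed decision tree, the per-species
    mutilation scoring rules, and assessment results for 17 anonymised
    textile standards as fixtures, plus generators for synthetic frameworks
    and answer sets, file readers/writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
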