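Package: iatfacets
Title: Many-Facet Rasch Decomposition of Implicit Association Test Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes the Implicit Association Test (IAT) effect with a
    many-facet Rasch measurement (MFRM) model. Trial-level response latencies
    are filtered, aggregated to a respondent x associative-condition x
    attribute-stimulus matrix and discretized into ordinal speed categories by
    global tertiles. A rating-scale MFRM is then estimated by joint maximum
    likelihood, giving interval measures (logits) for respondents, respondent
    groups, attribute stimuli and associative conditions together with standard
    errors, infit/outfit statistics, separation reliabilities and fixed
    all-same chi-square tests. Interaction (bias) analyses quantify
    differential condition and stimulus functioning, yield the IAT effect
    (the distance between the two condition measures) overall and per group,
    and support between-group contrasts. The conventional D2 latency score is
    provided as a cross-check, and a synthetic-data generator with known true
    parameters makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
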