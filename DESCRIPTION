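Package: trajage
Title: Life-Course Socioeconomic Trajectories and Blood-Based Biological Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how life-course socioeconomic trajectories relate to
    biological aging measured from routine blood markers. Provides a seeded
    synthetic-cohort generator with known ground truth; deterministic scoring of
    childhood, educational and adult socioeconomic position into eight
    life-course trajectories; marker quality control, Gower k-nearest-neighbour
    imputation and a feed-forward neural-network aging clock yielding biological
    age and its gap from chronological age (delta age); Mediterranean diet,
    dietary and lifestyle inflammation scores and SF-36 physical/mental
    components; incrementally adjusted linear association models; and
    regression-based counterfactual mediation analysis (natural direct and
    indirect effects, proportion mediated) with bootstrap percentile inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    arrow
Config/testthat/edition: 3
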