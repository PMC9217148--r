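Package: repostcascade
Title: Reconstruction and Analysis of Microblog Repost Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs repost cascades from raw microblog forward-chain
    records ("//"-delimited repost text), computes dissemination metrics
    (scale, depth, maximum and average width, speed), classifies cascade
    structure into radiation, sector and viral types, clusters posting
    users on authority features with k-means, and correlates cascade
    topology with creator authority by Spearman rank correlation.
    Includes a seeded branching-process simulator that emits raw repost
    tables with chain texts, so the full pipeline is testable without
    platform access, plus inter-coder reliability (Krippendorff's alpha)
    and per-topic descriptive summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
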