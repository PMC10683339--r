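Package: dtrlearn
Title: Dynamic Treatment Regimes from Two-Stage SMART Data by Modified
    Interactive Q-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Backward-induction estimation of two-stage dynamic treatment
    regimes from sequential multiple assignment randomized trial (SMART)
    data. Implements four linear-regression learners: standard Q-learning,
    modified Q-learning with a regret-adjusted pseudo-outcome, interactive
    Q-learning, and modified interactive Q-learning, which combines the
    regret adjustment with an interactive stage-1 model built from a
    main-effect regression and a fitted conditional distribution of the
    stage-2 treatment-effect contrast. Includes a synthetic SMART generator
    with heterogeneous treatment effects at both stages, potential-outcome
    population construction, evaluation metrics (probability of correctly
    identified stage-1 rules; bias of the estimated optimal value), and a
    Monte-Carlo omitted-variable-bias oracle for the stage-2 main-effect
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
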