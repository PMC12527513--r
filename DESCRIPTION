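Package: marcplot
Title: Meta-Analytic Rain Cloud Plots and Supporting Meta-Analysis Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Meta-Analytic Rain Cloud (MARC) plots — scatterplot
    displays of meta-analytic evidence that map effect-size magnitude to the
    x axis and relative inverse-variance weight to the y axis, with the
    pooled effect shown as a beeswarm "cloud" over its confidence interval —
    together with reference forest and bar layouts, fixed-effects pooling,
    a cluster-randomized-trial effect-size simulator with correlated
    lognormal sample sizes, and a confounded 4x4 factorial survey-experiment
    toolkit (design generation, questionnaire scoring, ANOVA/Tukey and
    mixed-model analysis). Layouts are fully resolved tibbles; renderers
    (static ggplot2 images and self-contained interactive HTML with hover
    text) add no computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
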