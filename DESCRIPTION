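Package: socialddm
Title: Drift-Diffusion Models of Social Perception and Altruistic Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-attribute drift-diffusion modelling of how people perceive
    others' merit and need and how those perceptions translate into altruistic
    action. Provides a two-boundary Wiener first-passage likelihood engine, a
    social-perception model that decomposes yes/no judgments into evidence
    biases and normative-evidence sensitivities, an altruistic-choice model
    with condition-dependent attribute weights (self, other, fairness),
    model-free generosity metrics with the cold-pressor buy-out rule, a
    cross-task individual-differences statistics layer (mixed-effects logistic
    regression, Wilcoxon contrasts, Spearman correlations with
    Benjamini-Hochberg correction, outlier screening, linking regressions),
    and seeded synthetic-data generators reproducing both task designs so the
    full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
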