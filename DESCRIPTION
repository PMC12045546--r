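Package: reconpref
Title: Simulated Elicitation and Analysis of Patient Preferences for
    Breast Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the three gold-standard health-state preference
    assessments used in breast reconstruction counseling - card ranking,
    visual analog scale rating, and standard-gamble titration with
    chained-gamble composition against death - for a synthetic cohort of
    women considering tissue-based, implant-based, or no reconstruction
    after mastectomy.  Provides a generative model of participant
    covariates and latent health-state utilities, a stochastic-choice
    respondent with iterative probability titration, and the complete
    downstream statistical pipeline: median/IQR summary tables, Spearman
    and Wilcoxon signed-rank comparisons between instruments,
    Kruskal-Wallis comparisons across body-mass-index categories, and
    univariate screening followed by backward Akaike-information-criterion
    selection of multivariable linear models of psychosocial covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
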