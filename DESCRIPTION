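Package: microwl
Title: Gut Microbiome Predictors of Long-Term Weight-Loss Success
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery and evaluation of small sets of bacterial taxa that
    predict long-term weight-loss success from baseline gut-microbiome
    relative abundances in small cohorts. Implements three complementary
    variable-selection avenues (per-taxon correlation screening, stability
    selection by repeated cross-validated elastic-net regression, and a
    Monte-Carlo search over multiple linear regression models with a
    weighted importance index), fuses them into a single candidate score,
    fits and cross-validates sparse k-term linear predictors of relative
    weight loss and change in BMI, and provides compositional ordination
    tools (centered log-ratio transform, PCA, Euclidean PERMANOVA,
    Mann-Whitney tests with FDR control). A synthetic-cohort generator with
    planted outcome-associated taxa makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
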