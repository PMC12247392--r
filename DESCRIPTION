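Package: mrpraking
Title: Small-Area Prevalence Estimation by Multilevel Regression with
    Raking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid small-area estimation combining multilevel (random
    intercept) logistic regression with raking-based estimation of joint
    population cell counts from marginal census distributions. Fits the
    random-intercept model by adaptive Gauss-Hermite quadrature, rakes
    per-area margins defined on arbitrary factor subsets by iterative
    proportional fitting, post-stratifies predicted cell probabilities
    with the raked counts, and attaches stratified case-resampling
    bootstrap percentile confidence intervals. Includes a synthetic-data
    generator emulating metro-area surveillance surveys and census
    margins, internal/external validation metrics, and a YAML-driven
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
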