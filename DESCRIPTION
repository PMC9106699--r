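Package: windmatch
Title: Matched-Pair Causal Inference for Wind-Driven Air Pollution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embeds observational daily air-quality time series within a
    hypothetical pairwise randomized experiment to estimate the effect of
    North-East winds on pollutant concentrations. Provides constrained
    bipartite pair matching without replacement (exact-match variables,
    covariate calipers, and date-gap rules motivated by the stable unit
    treatment value assumption), covariate balance diagnostics, Neymanian
    estimation of the matched average treatment effect with a conservative
    variance, Rosenbaum-style quantitative bias analysis (worst-case p-value
    bounds and Gamma-adjusted confidence intervals from the Wilcoxon
    signed-rank statistic), negative-control outcome checks, chained
    imputation of missing values, and a seeded synthetic daily-data
    generator with known potential outcomes for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    ranger,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
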