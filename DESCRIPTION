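Package: betaqtl
Title: Robust QTL Interval Mapping by Minimum Beta-Divergence
Version: 0.1.0
Authors@R:
    person("Ana", "Quintana", email = "ana.quintana@example.org",
           role = c("aut", "cre"))
Description: Interval mapping of quantitative trait loci (QTL) in backcross
    and F2 experimental populations, with a robust variant (BetaCIM) that
    maximises a beta-likelihood instead of the ordinary likelihood so that
    phenotypic outliers are down-weighted by the factor f(y)^beta. Provides a
    cross simulator (Haldane map function, no crossover interference,
    heritability-scaled phenotypes, outlier contamination), conditional
    QTL-genotype probabilities given flanking markers, an EM-type maximiser of
    the beta-likelihood for Gaussian mixture QTL models, genome scans for
    interval mapping (IM), composite interval mapping (CIM) and BetaCIM with
    stepwise cofactor selection, permutation-based genome-wide LOD thresholds,
    and K-fold cross-validation selection of the robustness tuning parameter
    beta.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
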