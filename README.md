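# betaqtl — robust QTL interval mapping by minimum beta-divergence

`betaqtl` maps quantitative trait loci (QTL) in backcross and F2
experimental populations and stays reliable when the phenotype contains
outliers. It implements classical interval mapping (IM), composite interval
mapping (CIM, i.e. IM with stepwise-selected background markers as
covariates), and a robust variant — **BetaCIM** — that estimates the
mixture model by maximising a *beta-likelihood* instead of the ordinary
likelihood. It is aimed at quantitative geneticists analysing experimental
crosses and at methodologists studying robust estimation in genome scans.

## The model in brief

At a test position, the phenotype of individual *j* follows a Gaussian
mixture over the unobserved QTL genotypes,

    f(y_j | θ) = Σ_i p_ji φ((y_j − μ_ji)/σ)/σ,   μ_ji = X_j γ + D_i·E,

where `p_ji` is the conditional probability of genotype class *i* given the
two flanking markers (Haldane map function, no interference), `D` is the
genetic design matrix (`x* ∈ {1,0}` for a backcross; `(x*, z*)` codings for
F2 additive and dominance effects), `E` the genetic effects and `X` the
covariates (intercept + cofactor marker codes). Parameters maximise

    L_β(θ) = (1/β) [ (1/n) Σ_j f(y_j|θ)^β / l_β,j − 1 ],
    l_β,j = [∫ f_j(y|θ)^{β+1} dy]^{β/(β+1)},

which reduces to the mean log-likelihood as β → 0 and down-weights
low-density observations by `f(y)^β` for β > 0 (maximising it minimises the
beta-divergence to the model, so the estimator's influence function is
bounded for β > 0). Evidence for a QTL is the beta-LOD,
`LOD_β = log10(e)·n·(L_β(alt) − L_β(null))`, assessed against a genome-wide
permutation threshold. The robustness parameter β is chosen per trait by
repeated K-fold cross-validation of a held-out divergence score under the
null model: clean traits select β at the bottom of the grid (≈ 0.001, i.e.
BetaCIM ≈ CIM), contaminated traits select substantially larger β.

The package also ships the cross simulator used for its validation studies
(maps, gamete-level genotype simulation, heritability-scaled phenotypes,
additive outlier contamination) plus evaluation helpers (detection power,
effect-estimation MSE).

## Worked example

Simulate the bundled four-QTL backcross design (n = 300, effects 2.12,
−1.23, −1.46, 1.74 at markers C1M3, C2M6, C3M4, C4M4, heritability 0.5),
contaminate 5% of phenotypes with large shifts, then run the robust scan:

```r
library(betaqtl)

cross <- simulate_scenario(unlinked_qtl_scenario(), seed = 42,
                           contamination = 0.05)
cof  <- select_cofactors(cross, trim_outliers = TRUE)
cv   <- select_beta(cross, cofactors = cof, seed = 42)
cv
#> <beta_cv> 10-fold CV, beta0 = 0.1; selected beta = 0.1

scan <- genome_scan(cross, method = "betacim", beta = cv$beta_opt,
                    cofactors = cof, step = 2)
thr  <- permutation_threshold(cross, "betacim", beta = cv$beta_opt,
                              cofactors = cof, n_perm = 100, seed = 42,
                              step = 10)
thr
#> <qtl_threshold> betacim genome-wide 95% threshold = 1.608 (100 permutations)

call_peaks(scan, thr)
#> # A tibble: 4 × 5
#>   chrom   pos   lod marker marker_pos
#>   <chr> <dbl> <dbl> <chr>       <dbl>
#> 1 1        20 15.0  C1M3           20
#> 2 2        54  3.50 C2M6           50
#> 3 3        32  6.56 C3M4           30
#> 4 4        30 20.5  C4M4           30
```

Despite the contamination, the cross-validated β (0.1) lets the scan
recover all four simulated loci at (or one grid step from) their true
positions; the same data analysed with `method = "im"` or `"cim"` loses
most of them below threshold. `autoplot(scan, thr)` draws the LOD profile,
and `tidy()` / `glance()` work on fits and CV objects. A thin command-line
wrapper lives at `inst/cli/betaqtl` (subcommands `sim`, `scan`, `cv`,
`perm`, `reproduce`).

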