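---
title: "Robust QTL interval mapping by minimum beta-divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust QTL interval mapping by minimum beta-divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaqtl)
```

## The problem

Quantitative trait locus (QTL) mapping in experimental crosses (a backcross
with two genotype classes per locus, or an F2 intercross with three) tests,
at each position of a genetic map, whether the genotype of a putative locus
explains variation in a quantitative phenotype. Because the locus is only
observed indirectly — through linked flanking markers — the phenotype is
modelled as a finite Gaussian mixture over the possible QTL genotypes, with
mixing weights given by the conditional probability of each genotype given
the flanking markers. Interval mapping (IM) fits this mixture by maximum
likelihood; composite interval mapping (CIM) adds a set of background
markers ("cofactors") as covariates so that linked and unlinked QTLs outside
the tested interval do not bias the test.

Maximum likelihood, however, is not robust: a handful of grossly wrong
phenotype values (recording errors, environmental accidents) can destroy
both the genome-wide LOD profile and the effect estimates. The robust method
implemented here — BetaCIM — replaces the log-likelihood with a
*beta-likelihood*, the empirical objective whose maximisation minimises the
beta-divergence to the model. Each observation enters estimation weighted by
`f(y_j)^beta`, so points with low model density are automatically
down-weighted. As `beta -> 0` the method reduces continuously to classical
IM/CIM.

## Model and objective

For individual `j` with covariate row `X_j` (intercept, optional covariates,
cofactor marker codes) the phenotype density is

```
f(y_j | theta) = sum_i p_ji  phi((y_j - mu_ji)/sigma) / sigma,
mu_ji = X_j gamma + D_i . E
```

where `p_ji` are the flanking-marker conditional genotype probabilities, `D`
is the genetic design matrix (backcross single-QTL coding `x* in {1, 0}`; F2
coding `(x*, z*)` = `(1, -1/2)`, `(0, 1/2)`, `(-1, -1/2)` for QQ/Qq/qq), `E`
the genetic effects (additive `a`, and dominance `d` for F2) and `gamma` the
covariate coefficients. For `k` loci considered jointly the design grows to
`2^k x k` (backcross, entries ±1/2) or `3^k x 2k` (F2), with optional
epistasis columns as products of main-effect columns; the joint mixing
probabilities are row-wise outer products of the single-interval ones
(independence holds under no crossover interference).

The estimation objective is the per-observation-mean beta-likelihood

```
L_beta(theta) = (1/beta) [ (1/n) sum_j f(y_j)^beta / l_beta,j  - 1 ],
l_beta,j = [ ∫ f_j(y)^(beta+1) dy ]^(beta/(beta+1))
```

Because `∫ f^(beta+1) -> 1` and its log has zero derivative at `beta = 0`,
`l_beta = 1 + O(beta^2)` and `L_beta -> (1/n) sum log f(y_j)`: the classical
mean log-likelihood is the exact `beta -> 0` limit, which the test suite
checks numerically at `beta = 1e-8`. Evidence for a QTL at a position is

```
LOD_beta = log10(e) * n * (L_beta(alt) - L_beta(null))
```

which at `beta = 0` is the classical LOD. For `beta > 0` the alternative and
null objectives are not nested, so slightly negative values can occur; they
are reported as computed and floored at zero only for plotting.

### Why this is robust

The estimating function (gradient of the per-observation objective) carries
the factor `f(y)^beta`: every component behaves like `exp(-beta z^2)` times
a polynomial in the standardised residual `z`, hence is bounded for
`beta > 0` and unbounded at `beta = 0`. The package verifies this property
numerically rather than symbolically: `psi_bounds()` evaluates the gradient
over a wide phenotype grid and reports each component's supremum and where
it is attained (interior for `beta > 0`; boundary-growing for `beta = 0`).

## The EM-type maximiser

`beta_em_fit()` alternates:

* **E-step** — beta-weighted posteriors `Pi_beta[j,i] = pi_ji f(y_j)^beta`,
  where `pi_ji` is the ordinary posterior class probability. Rows sum to
  `f(y_j)^beta`, the robustness weight of observation `j`; at `beta = 0`
  they are ordinary posteriors.
* **M-step** — the genetic effects solve the weighted normal equations
  `V E = b` with `V[i,i'] = 1' Pi_beta (D_i # D_i')` and
  `b = (y - X gamma)' Pi_beta D`; `gamma` is the `f^beta`-weighted
  least-squares update; `sigma^2` is the `(1 + beta)`-scaled weighted
  residual quadratic form. The one-sweep Jacobi recurrence `E <- m - M E`
  for the same equations is available via `effects_update = "recurrence"`;
  both have the same fixed point and the direct solve is the default
  because it maximises the M-step objective exactly.

For the null (single Gaussian) model the normaliser has the closed form
`[(2 pi sigma^2)^(-beta/2) (1+beta)^(-1/2)]^(beta/(beta+1))`; the fixed
point of the iteration is then exactly a stationary point of the objective,
which is how the `(1 + beta)` variance factor arises. For genuine mixtures
the normaliser is integrated by Simpson quadrature on
`[min mu - 8 sigma, max mu + 8 sigma]` (default 401 points; the integrand is
translation invariant, so only the genetic offsets matter). The test suite
requires the closed form and quadrature to agree to 1e-8 and the objective
trace to be non-decreasing to within 1e-10 on every fixture.

Initialisation is deterministic (OLS of `y` on `X`; effects from OLS of the
residuals on the expected genotype codes `Q D`; residual variance), which
gives a good basin for the unimodal single-position fits a scan performs and
makes every run reproducible. Convergence is declared at a relative
objective change below 1e-8 (cap 200 iterations; non-convergence is flagged
on the result, not raised).

## Scans, cofactors, thresholds

`genome_scan()` walks a cM grid (default step 1), builds the conditional
probabilities from the two flanking markers by exact gamete enumeration
under the Haldane map function `r = (1 - exp(-2d/100))/2` — the map function
is implied by the no-interference assumption — and records `LOD_beta`
against a cached null fit. Cofactors are chosen by forward stepwise
regression on additive marker codes with the BIC (stop when BIC stops
improving; default cap `min(10, 2 sqrt(n)/ln n)`). At each test position,
cofactors within ±10 cM (configurable) are dropped so the tested interval is
not explained away by its own neighbourhood. Cofactor adjustment uses
additive codes only (backcross `{1,0}`, F2 `{1,0,-1}`); dominance cofactor
columns are omitted.

Least-squares stepwise selection is itself outlier-sensitive, so the robust
path (`method = "betacim"`) can exclude observations outside the quartile
fence `[Q1 - 3 IQR, Q3 + 3 IQR]` from the *selection step only*
(`trim_outliers = TRUE`); all observations re-enter the subsequent robust
fits. For the dense ten-QTL linked design studied below, the conservative
default cofactor cap under-covers the background (six markers for ten QTLs)
and leaves visible bias in the effect estimates; `linked_mse_study()`
therefore lifts the cap to `sqrt(n)` and lets the BIC stop on its own
(around eleven markers in practice).

Genome-wide significance uses the standard permutation scheme: shuffle the
phenotype, rerun the entire scan, take the `1 - alpha` quantile of the
maximum LOD (`quantile()` type 7). Beta and the cofactor set are held at the
values selected on the observed data — re-selecting beta per permutation is
supported by the same machinery but costs an order of magnitude more and
changes thresholds little.

## Choosing beta by cross-validation

`cv_select_beta()` selects the robustness parameter on the *null* model
(intercept + cofactors): K-fold cross-validation (default `K = 10`) fits the
beta-weighted Gaussian regression on each training set and scores the
held-out fold with the fixed-`beta0` divergence measure (default
`beta0 = 0.1`), whose `beta0 -> 0` limit is the negative mean held-out
log-likelihood. The selected beta minimises the fold-aggregated score; ties
break to the smallest beta. The default grid is
`{0.001, 0.005, 0.01, 0.02, 0.041, 0.06, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5}`.

On clean data the penalty for a too-large beta is only the estimator's
efficiency loss — a second-order effect — so a single fold assignment yields
a noisy argmin. The score curve is therefore averaged over five independent
fold assignments (repeated CV, `repeats = 5`); with this default the median
selected beta over clean simulated datasets is the grid floor 0.001, and
contaminated datasets move the selection up the grid. One caveat observed in
simulation: once outliers are extreme (the 8-SD shifts below), every beta in
roughly `[0.06, 0.3]` down-weights them equally well, so the selected beta
plateaus rather than growing steadily with the contamination rate; the
clean-versus-contaminated contrast is the reliable signal.

## The simulator and the study designs

`sim_map()`, `sim_cross()` and `sim_phenotype()` emulate the standard
experimental-cross simulation: equally spaced markers, gametes generated
marker-to-marker with Haldane recombination probabilities and no
interference, and phenotypes `y = g + e` where `g` sums the coded QTL
effects and the residual variance is scaled from the *realised* sample
variance of `g` so each replicate attains the target heritability exactly by
construction. Contamination (`contaminate()`) shifts exactly
`round(rate * n)` randomly chosen observations by
`Normal(8 s, (2 s)^2)` in units of the clean phenotype SD `s` — far beyond
the `Q3 + 3 IQR` outlier fence. The magnitude is a package default (the
sources that motivate the design say only that random numbers were added);
power for *non-robust* methods on contaminated data depends strongly on it,
robust results do not.

Two bundled designs drive the reproduction studies:

* **Unlinked design** (`unlinked_qtl_scenario()`): backcross, 4 chromosomes
  × 15 markers at 10 cM, `n = 300`, additive effects 2.12, −1.23, −1.46 and
  1.74 at markers C1M3, C2M6, C3M4 and C4M4, heritability 0.5.
* **Linked design** (`linked_qtl_scenario()`): backcross, 4 chromosomes ×
  16 markers at 10 cM, `n = 300`, ten QTLs (three per chromosome on 1–3, one
  on 4) with effects between −1.46 and 1.61, total heritability 0.7. The
  chromosome-4 locus sits at 40 cM.

`unlinked_power_study()` reports detection power (fraction of replicates
whose LOD at a true QTL marker exceeds the genome-wide 5% permutation
threshold) and the mean/SD of effect estimates; `linked_mse_study()` reports
the mean squared error of the ten jointly mapped effects,
`MSE = (1/10) sum (a_i - a_hat_i)^2`, estimated CIM-style by one
single-QTL fit per position with cofactors outside the exclusion window.

### Problem sizes used by the tests and the acceptance script

The packaged studies run at desk scale: 20 replicates per power study (the
original studies use 100), 100 permutations per threshold (originally
1000) computed once per scenario × method on a representative replicate and
reused, scans at marker resolution (10 cM step; the true loci sit at
markers), 10 seeds for each MSE average, and 50 datasets for the
beta-selection median. At these sizes the full acceptance run takes a few
minutes on one CPU. Monte-Carlo error at 20 replicates is about ±11
percentage points (SE) for a power near 50% and ±0.05 for mean effect
estimates.

### What the simulations do and do not show

The generator matches the assumptions of the estimator (Gaussian residuals,
no interference, fully typed markers, additive contamination). Passing these
studies shows the machinery is internally correct and robust in the designed
sense; it does not certify behaviour under missing genotypes, genotyping
error, non-Gaussian trait distributions, segregation distortion or selective
genotyping, none of which are modelled (missing genotypes are rejected at
input).

## Numerical choices and degenerate inputs

* All mixture densities and posteriors are computed in log space; underflow
  with large `beta * n` is avoided by factoring `f^beta` as
  `exp(beta * logf)`.
* At a typed marker the conditional probabilities are exact unit vectors and
  the mixture degenerates to a single Gaussian; the normaliser then takes
  its closed form (no quadrature) and the EM converges in a couple of
  iterations.
* `sigma^2` updates are floored at 1e-12; singular effect systems or
  weighted `X'X` raise a degenerate-fit error naming the offending columns;
  per-position scan failures are recorded as `NA` with a warning and the
  scan continues.
* Scan grids include each chromosome's terminal marker exactly once;
  positions match markers within 1e-8 cM.
* Peak calling keeps local maxima above threshold separated by at least one
  median marker interval, ties resolved towards the lower cM position.
* Negative `LOD_beta` values (possible for `beta > 0`) are preserved in
  results; `autoplot()` floors them at zero for display.

## Known limitations

* Conditioning uses the two flanking markers (the classical interval-
  mapping model), not a multipoint hidden Markov chain; with dense fully
  typed maps the difference is negligible, with sparse or error-prone maps
  it is not.
* Missing genotypes, X-chromosome inheritance, RIL/4-way crosses and
  crossover interference are out of scope.
* The beta-LOD permutation threshold is recomputed per dataset; no
  analytical null approximation is provided.
* Joint multi-QTL fitting is exposed through the design-matrix and joint-
  probability machinery (`design_matrix(k)`, `joint_qtl_probs()`) and
  tested at small `k`; automated multiple-QTL model search is not
  implemented.
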