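# lderge

Estimates the proportion of phenotypic variance explained by genome-wide
gene-environment (GE) interactions from genome-wide interaction scan
(GWIS) summary statistics and block-wise linkage-disequilibrium (LD)
information — no individual-level genotypes needed at estimation time.
It is aimed at statistical geneticists working with biobank-scale
interaction scans who want a variance-component estimate of G×E with
honest standard errors.

## Method in brief

Under a polygenic interaction model with standardized genotypes `G`,
standardized exposure `E`, product terms `S = G ∘ E` and interaction
effects `γ_j ~ N(0, h²_I / M)`, the GWIS interaction Z-scores satisfy

    E(Z Zᵀ) = N h²_I L / M + (c + (K(E) − 1)(h²_I + σ²₁)) R,

with `R` the LD matrix, `L = RᵀR` the LD-score matrix, `N` the sample
size, `K(E)` the exposure kurtosis, `σ²₁` the residual-by-exposure
interaction variance and `c` an unconstrained confounding intercept.
LD-score-style baselines regress `z²_j` on the diagonal of `L`. The
estimator here (LDER-GE) instead eigen-decomposes each LD block,
`R = U D Uᵀ`, whitens the scores `z̃ = D^{-1/2} Uᵀ z`, and fits

    E(z̃²_j) = N h²_I d_j / M + (c + 2 (h²_I + σ²₁))

by iterative weighted least squares with weights
`min(d_j, 1) / (N h²_I d_j / M + intercept)²`, which uses the full LD
matrix and is markedly more precise than the diagonal baseline.
Standard errors come from a delete-block jackknife; inference is a
one-sided Wald test. Binary traits can be mapped to the liability scale
(Robertson or Lee multipliers), and interaction variance over several
covariates can be aggregated after sequential residualization. A
simulation engine (block-LD genotypes, the generative phenotype model,
and a direct moment-model summary-statistic sampler) supports
calibration studies. The diagonal baseline itself is included as
`ldsc_ge_fit()` for comparison.

## Worked example

Simulate interaction summary statistics on a blocky synthetic panel with
a true GE variance of 2% and recover it:

```r
library(lderge)
set.seed(2025)

panel <- synthetic_panel(n_blocks = 40, block_size = 50, rho = 0.9)
stats <- simulate_sumstats_direct(panel, n = 20000, h2_I = 0.02, intercept = 1.04)
fit   <- lderge_fit(transform_zscores(stats, panel), n = 20000, m = 2000)
fit
#> <lderge_fit: lder_ge>
#>   h2_I      =  0.015657
#>   intercept =  1.115613
#>   se        = 0.002989
#>   p (one-sided) = 8.123e-08
#>   components = 2000, jackknife groups = 40, iterations = 5

tidy(fit)
#> # A tibble: 2 × 5
#>   term      estimate std.error statistic       p.value
#>   <chr>        <dbl>     <dbl>     <dbl>         <dbl>
#> 1 h2_I        0.0157   0.00299      5.24  0.0000000812
#> 2 intercept   1.12    NA           NA    NA
```

The point estimate (0.0157 ± 0.0030) covers the generative value 0.02
at two standard errors on this single draw, and the interaction signal
is detected at p ≈ 8×10⁻⁸. The fitted intercept estimates the composite
`c + 2(h²_I + σ²₁)`, not `c` alone. The same statistics through the
diagonal baseline give a four-fold larger standard error on this panel
and no detection:

```r
glance(ldsc_ge_fit(stats, panel_ld_scores(panel), n = 20000, m = 2000,
                   block_id = rep(1:40, each = 50)))[, c("h2_I", "se", "p_value")]
#> # A tibble: 1 × 3
#>      h2_I     se p_value
#>   <dbl>  <dbl>   <dbl>
#> 1 0.00122 0.0120   0.460
```

For real data the entry points are `read_sumstats()` (tab-delimited
GWIS output with `Z_INT` or `BETA_INT`/`SE_INT` columns),
`align_alleles()` against the panel's variant table, `build_panel()` /
`save_panel()` / `load_panel()` for the eigen-system reference, and the
`exec/lderge` script (`panel`, `fit`, `simulate` subcommands) for shell
use. `liability_scale(fit, K, P)` converts binary-trait estimates;
`sequential_residualize()` + `aggregate_ge_variance()` handle
multi-covariate totals.

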