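# woolres

Genetic analysis of resilience in sheep from two longitudinal data sources:
wool fibre diameter (FD) measured at 5 mm increments along the staple — a
continuous diary of growth conditions between birth and wool sampling — and
repeated body weights (BW). The package is for quantitative geneticists and
breeding-program analysts who want per-animal resilience phenotypes from
longitudinal records together with their heritabilities and genetic
correlations.

## What it computes

Records are standardized within flock-year (and recording moment for BW),
smoothed into penalized B-splines

$$\min_c \; \sum_{j=1}^n \big[y_j - x(c,t_j)\big]^2 \;+\; \lambda \int_0^L \big[\partial^2 x(c,t)\big]^2\,dt,$$

and phase-aligned within flock-year by square-root velocity function (SRVF)
elastic registration: each curve's SRVF $q = \mathrm{sign}(\dot f)\sqrt{|\dot f|}$
is warped onto the flock-year Karcher mean $\mu_k$ by the optimal monotone,
endpoint-preserving warp

$$\gamma^* = \arg\min_{\gamma\in\Gamma}\ \lVert \mu_k - (q\circ\gamma)\sqrt{\dot\gamma}\rVert^2 + \lambda_a \lVert\sqrt{\dot\gamma}-1\rVert^2,$$

solved by dynamic programming. From the deviations of each aligned curve
around its group mean come four general resilience indicators — log-variance
(Lnvar), lag-1 autocorrelation (Auto), skewness, mean absolute change (ABS) —
and, over the weaning collapse-and-recovery window detected on the group
mean, three weaning-specific ones: response and recovery rates
(ROC_response, ROC_recovery) and the area between the animal's curve and the
group mean (ABC). Variance components come from single-step animal models

$$y = Xb + Z_1 a + Z_2 m + e,\qquad a\sim N(0, H\sigma^2_a),\ m\sim N(0, I\sigma^2_m),\ e\sim N(0, I\sigma^2_e),$$

fitted by REML through sparse mixed-model equations, where $H$ blends the
pedigree numerator matrix $A$ with a VanRaden genomic matrix $G$
($G_w = 0.95\,G + 0.05\,A_{22}$). Bivariate models give genetic and
phenotypic correlations with ±2 SE significance.

A fully synthetic data generator (`sim_config()`, `simulate_pedigree()`,
`simulate_genotypes()`, `simulate_effects()`, `simulate_series()`) emulates
the data structure — flock-year groups, irregular FD/BW records, a weaning
dip scaled by heritable susceptibility, random disturbances, individual
phase variation — so the entire pipeline is testable against a known truth.

## Worked example

```r
library(woolres)

cfg <- pipeline_config(
  sim = sim_config(n_flock_years = 4, animals_per_group = 40,
                   n_dams_per_group = 20, dip_flock_year_fraction = 0.5,
                   seed = 42))
res <- run_pipeline(cfg)            # simulate ... varcomp
tab <- report_tables(res)

tab$h2_table[, c("series", "trait", "n", "mean", "sd", "h2", "h2_se")]
#>   series trait   n       mean        sd h2 h2_se
#> 1     FD Lnvar 157 -2.4918825 1.2129487  0     0
#> 2     BW Lnvar 159 -0.6987718 0.8665092  0     0

subset(tab$windows, series == "FD")
#>   series flock_year lambda detected t_w t_min t_max
#> 1     FD       FY01    0.2    FALSE  19    NA    NA
#> 2     FD       FY02    0.2    FALSE  21    NA    NA
#> 3     FD       FY03    0.2     TRUE  20    26    39
#> 4     FD       FY04    0.2     FALSE 20    NA    NA

res$sim$flock_years                 # the generator's ground truth
#>   flock_year dip_present mean_weaning_age
#> 1       FY01       FALSE         87.99627
#> 2       FY02       FALSE         88.08175
#> 3       FY03        TRUE         90.49568
#> 4       FY04       FALSE         91.01068

ln <- merge(subset(res$traits$traits, series == "FD" & trait == "Lnvar" & lambda == 0.2),
            res$sim$truth, by = "animal")
cor(ln$u_FD, ln$value, method = "spearman", use = "complete.obs")
#> [1] 0.4593874
```

The window registry shows the weaning collapse-and-recovery window
(positions in mm along the staple) detected on each flock-year mean curve:
the detector flags exactly the one group simulated with a weaning
disturbance, and animals in undetected groups get missing weaning traits.
The rank correlation of 0.46 between the generator's true susceptibility
and the FD log-variance indicator shows the phenotype ranks animals as
intended. The heritability estimates sit at the boundary (0) here because
157 animals cannot resolve an h² of 0.1 — the suite's validation runs use
thousands of animals, where estimates centre on the simulated truth.

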