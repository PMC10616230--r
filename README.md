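# vpdgrowth

Tools for quantifying how boreal tree growth responds to atmospheric
dryness. Starting from daily weather (Tmin, Tmax, precipitation,
optionally relative humidity) and dated annual ring widths, the package:

1. derives daily **vapour pressure deficit** (VPD, kPa; Tetens saturation
   curve) and a **soil moisture index** (percent of a 400 mm water-holding
   capacity, from a daily quadratic-plus-linear water balance driven by
   precipitation and simplified Penman–Monteith evapotranspiration), and
   aggregates both to summer (June–August) site-year means plus long-term
   climatologies (MAT, MAP, mean summer SMI);
2. converts ring widths to **basal area increments**
   (BAI<sub>t</sub> = πR<sub>t</sub>² − πR<sub>t−1</sub>², cm²), excluding
   the first ten juvenile rings;
3. fits, per site and species, a penalized-spline mixed model

   log BAI<sub>it</sub> = α·log BA<sub>i,t−1</sub> + s(age<sub>it</sub>)
   + β₁·VPD<sub>t</sub> + β₂·VPD<sub>t−1</sub> + b<sub>i</sub> + e<sub>it</sub>,

   with a tree random intercept b<sub>i</sub> and AR1 residuals e<sub>it</sub>,
   by iterated whitened penalized least squares with REML smoothness
   selection, and classifies each site's VPD response from the Wald
   t-values (negative / positive / nonsignificant / nonconvergent);
4. attributes the significant t-values to seven site predictors
   (elevation, MAT, MAP, summer SMI, species, mean tree age, mean basal
   area) with a 500-tree bagged regression forest reporting unscaled OOB
   permutation importance, average minimal depth, root-node counts and
   partial dependence;
5. computes species-level **growth change** (percent deviation from an
   age/size-detrended prediction) with Moran's-I-corrected confidence
   intervals, effective-sample-size trend tests, stationary-block-bootstrap
   correlation intervals, and inverse-distance-weighted maps of t-values
   on a 1° grid.

A synthetic-data module generates coupled weather and ring-width fixtures
from the same growth model with known ground truth, so the whole chain is
testable without any external data. See the methods vignette
(`vignettes/growth-vpd-methods.Rmd`) for the estimator, parameter
defaults, conventions, and known limitations.

## Worked example

```r
library(vpdgrowth)

# one site's weather -> summer climate covariates
p  <- site_params(mat = 2)                       # boreal site, MAT 2 degC
wx <- simulate_daily_weather(p, 1959:2018, seed = 42)
daily <- derive_daily_climate(wx, list(lat = 52, elev = 300))
sc <- summarize_site_climate(daily, 1959:2018, "S001", lat = 52, lon = -93.5)
head(sc[, 1:6], 3)
#>   site_id year vpd_summer smi_summer   mat     map
#> 1    S001 1959      0.636     62.324 2.105 785.479
#> 2    S001 1960      0.617     75.063 2.105 785.479
#> 3    S001 1961      0.651     71.539 2.105 785.479

# five trees grown with a true prior-summer VPD effect beta2 = -1 per kPa
cfg <- sim_config(n_sites = 1, trees_per_site = 5, seed = 7)
rs  <- simulate_ring_series(cfg, sc, site_id = "S001",
                            species = "PICEMAR", seed = 7)
bai <- lapply(lapply(rs$series, widths_to_bai), apply_juvenile_filter)
fit <- fit_growth_gamm(prepare_model_frame(bai, sc))
fit
#> <growth_model_fit> site S001 / PICEMAR: n=225 obs, 5 trees
#>             estimate     se       t      p
#> (Intercept)  -1.1087 0.3676 -3.0163 0.0029
#> alpha         0.8344 0.0566 14.7411 0.0000
#> beta1        -0.1885 0.2305 -0.8178 0.4144
#> beta2        -1.0339 0.2407 -4.2963 0.0000
#> phi=0.472 sigma_tree=0.000 sigma_eps=0.237 lambda=6.56e+07 edf(s)=1.00 r2=0.791

classify_response(fit)
#>   site_id species    class_vpd_t class_vpd_t1   t_vpd_t t_vpd_t1
#> 1    S001 PICEMAR nonsignificant     negative -0.817798 -4.29634
```

Reading the output: the generating prior-summer effect (−1 per kPa) is
recovered as β̂₂ = −1.03 ± 0.24 and the site is classified *negative* for
VPD<sub>t−1</sub> — growth falls about 10% for every 0.1 kPa of
prior-summer atmospheric drying. The current-summer effect (true −0.4) is
present but not separable from noise at this sample size, a realistic
outcome for a 5-tree site. The AR1 coefficient (true 0.5) is estimated at
0.47; `r2 = 0.79` is the squared correlation between observed and fitted
log-BAI fluctuations.

The one-command synthetic end-to-end run:

```r
cfg <- pipeline_config(out_dir = "demo_run", seed = 1,
                       synthetic = sim_config(n_sites = 10, seed = 1))
run_pipeline(cfg)      # writes fixtures, fits, drivers, trends, manifest
summarize_run("demo_run")
```

or from the shell:

```sh
Rscript -e 'vpdgrowth::pipeline_cli()' run-all --out demo_run --seed 1
Rscript -e 'vpdgrowth::pipeline_cli()' report --run demo_run
```

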