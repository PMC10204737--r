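# siftraits

Retrieval of photosynthetic functional traits — electron transport rate
(ETR), maximum carboxylation rate (Vcmax) and stomatal conductance (gs)
— from canopy **sun-induced chlorophyll fluorescence (SIF)** time
series, for C3 crops such as paddy rice.

SIF is a radiance signal re-emitted by chlorophyll during
photosynthesis. Whereas simple approaches regress Vcmax directly on
SIF, `siftraits` implements a semimechanistic chain:

1. **qL–PAR law.** The fraction of open PSII reaction centers follows
   an exponential decline with irradiance, `qL = a·exp(b·PAR)`, fitted
   by nonlinear least squares to (qL, PAR) pairs.
2. **SIF → ETR.** The nonlinear fluorescence mechanism

   `ETR = qL · ΦPSIImax(1 + kDF) / [(1 − ΦPSIImax) · ε] · SIF`

   with ΦPSIImax the maximum PSII photochemical yield (0.83), kDF the
   thermal-dissipation/fluorescence rate-constant ratio (19), and
   ε ≈ NIRv/FPAR the canopy fluorescence escape probability.
3. **ETR → Vcmax.** Evolutionary-optimality coordination of the FvCB
   model (Ac = Aj) gives `Vcmax = ETR·m/(4·mc)` with
   `m = (Ci−Γ*)/(Ci+2Γ*)` and `mc = (Ci−Γ*)/(Ci+Km)`.
4. **ETR → gs.** Electron-use efficiency plus Fick's law:
   `gs = 0.4·m·ETR/(Ca−Ci)`.

The package also ships the linear SIF–Vcmax baseline, evaluation
metrics (R², MAE, RMSE, regression slope, MAE-based accuracy
improvement), a ±10% one-at-a-time parameter sensitivity analysis with
closed-form elasticity cross-checks, and a forward simulator that
generates synthetic seasons from known trait trajectories so the whole
chain can be tested end to end without field data.

## Worked example

```r
library(siftraits)

season <- simulate_season(sim_config())        # synthetic 120-day season
ql     <- fit_ql_par(generate_ql_pairs(seed = 42))
ql
#> qL-PAR exponential model: qL = 0.91914 * exp(-0.00103285 * PAR)
#>   fit: R2 = 0.9902 on n = 40 pairs

traits <- retrieve_series(season$series, ql, photo_params())
as.data.frame(traits)[35:37, ]
#>    year doy epsilon     ql   etr vcmax     gs
#> 35 2017 184  0.4041 0.5662 197.3 133.8 0.4270
#> 36 2017 185  0.4056 0.5649 176.8 119.8 0.3825
#> 37 2017 186  0.4069 0.5636 185.0 125.4 0.4003

evaluate(season$truth$vcmax, traits$vcmax)
#> n = 120  R2 = 0.991  MAE = 2.662  RMSE = 3.892  slope = 0.995  intercept = 0.4867
evaluate(season$truth$gs, traits$gs)
#> n = 120  R2 = 0.991  MAE = 0.008499  RMSE = 0.01242  slope = 0.995  intercept = 0.001554
```

Mid-season the retrieval reports an escape probability around 0.40, qL
around 0.56 at 480–500 W m⁻² PAR, ETR near 190 μmol m⁻² s⁻¹, Vcmax
120–135 μmol m⁻² s⁻¹ and gs ≈ 0.4 mol m⁻² s⁻¹ — the magnitudes
expected for a healthy rice canopy at its seasonal peak. Through 5%
multiplicative SIF noise the chain recovers the true traits with
R² = 0.99 and a regression slope within 1% of unity.

Parameter sensitivity:

```r
analytic_elasticities(photo_params())
#>    e_phi    e_kdf
#> 5.882353 0.950000
```

A 1% error in ΦPSIImax moves every retrieved trait by ~5.9%, versus
~0.95% for kDF: the PSII yield must be set accurately, the rate-constant
ratio is forgiving.

```r
improvement_percent(19.02, 11.29)
#> 40.64143
```

the MAE-based accuracy improvement of the mechanistic retrieval over
the linear baseline for the published field comparison.

## Command line

A thin launcher wraps the same functions, one subcommand per stage:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "siftraits.R", package = "siftraits"))')
Rscript $CLI simulate --seed 42 --out sim/
Rscript $CLI fit-ql   --input sim/ql_pairs.csv --out fitted.yml
Rscript $CLI estimate --input sim/series.csv --config fitted.yml --out traits.csv
Rscript $CLI sensitivity --input sim/series.csv --config fitted.yml --out sens.csv
Rscript $CLI show-config
```

Every run writes a `*.manifest.json` with the resolved parameters,
their hash, input/output paths and the seed.

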