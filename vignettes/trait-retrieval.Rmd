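---
title: "Semimechanistic retrieval of Vcmax and gs from canopy SIF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semimechanistic retrieval of Vcmax and gs from canopy SIF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siftraits)
```

## The model

Canopy sun-induced chlorophyll fluorescence (SIF, mW m⁻² nm⁻¹ sr⁻¹) is
emitted during the light reactions of photosynthesis and is therefore
informative about the electron transport rate (ETR). `siftraits`
implements a four-step semimechanistic chain from SIF to the two
functional traits that control C3 leaf photosynthesis, the maximum
carboxylation rate (Vcmax) and stomatal conductance (gs).

**Step 1 — qL(PAR).** The fraction of open PSII reaction centers
("lake" model qL) declines nonlinearly with irradiance as reaction
centers close. We model it as

$$q_L = a\,e^{b\,\mathrm{PAR}}, \qquad a > 0,\; b \le 0,$$

fitted by nonlinear least squares to a user-supplied table of
(qL, PAR) pairs (`fit_ql_par()`). Such pairs typically come from
radiative-transfer/biochemistry simulations or from pulse-amplitude
modulated fluorometry; the module is data-in, so either source works.

**Step 2 — SIF to ETR.** Partitioning absorbed light among
photochemistry, fluorescence and constitutive thermal dissipation with
rate-constant ratio $k_{DF} = k_D/k_F$ yields

$$\mathrm{ETR} = q_L(\mathrm{PAR}) \cdot
  \frac{\Phi_{PSIImax}\,(1 + k_{DF})}{(1-\Phi_{PSIImax})\,\varepsilon}
  \cdot \mathrm{SIF},$$

where $\varepsilon \approx \mathrm{NIRv}/\mathrm{FPAR}$ is the
probability that an emitted fluorescence photon escapes the canopy
toward the sensor. The relation is linear in SIF at a fixed state; the
nonlinearity enters through $q_L(\mathrm{PAR})$, which is what makes
this chain more than a regression. At the defaults
($\Phi_{PSIImax} = 0.83$, $k_{DF} = 19$) the scaling constant
$\Phi(1+k_{DF})/(1-\Phi)$ equals $97.647$.

**Step 3 — ETR to Vcmax.** Under the evolutionary-optimality
(co-limitation) assumption $A_c = A_j$ of the FvCB model, with
$A_c = V_{cmax}\, m_c$ and $A_j = (\mathrm{ETR}/4)\, m$,

$$V_{cmax} = \frac{\mathrm{ETR}\cdot m}{4\,m_c}, \qquad
  m = \frac{C_i - \Gamma^*}{C_i + 2\Gamma^*}, \quad
  m_c = \frac{C_i - \Gamma^*}{C_i + K_m}.$$

The factor 4 follows from the electron stoichiometry of RuBP
regeneration ($A_j = (\mathrm{ETR}/4)\,m$): carrying the algebra of
$A_c = A_j$ through forces the division by 4, and without it
default-parameter retrievals would give $V_{cmax} \approx 2.7\,
\mathrm{ETR}$, far outside the magnitudes observed for rice canopies
(peaks near 130 μmol m⁻² s⁻¹). We therefore implement the co-limitation
algebra exactly.

**Step 4 — ETR to gs.** Net assimilation equals ETR times the
electron-use efficiency of C3 photosynthesis, $A =
(\mathrm{ETR}/4)\,m$; equating with Fick's law $A = g_s (C_a - C_i)/r$,
where $r$ is the water-to-CO₂ diffusivity ratio, gives

$$g_s = \frac{r}{4}\cdot\frac{m\,\mathrm{ETR}}{C_a - C_i}
      = 0.4\,\frac{m\,\mathrm{ETR}}{C_a - C_i} \text{ at } r = 1.6 .$$

The constant 1.6 is sometimes loosely described as a pressure term in
this literature; dimensional analysis of the two expressions for $A$
identifies it as the diffusivity ratio, and that is how the package
names and exposes it (`diffusivity_ratio`).

## Parameters, units, defaults

| key | meaning | unit | default | why |
|---|---|---|---|---|
| `phi_psii_max` | max PSII photochemical yield | – | 0.83 | converged value for unstressed C3 leaves |
| `k_df` | $k_D/k_F$ | – | 19 | standard constant for chlorophyll in vivo |
| `ci` | intercellular CO₂ | μmol mol⁻¹ | 280 | 0.7 × Ca, typical C3 operating point |
| `ca` | ambient CO₂ | μmol mol⁻¹ | 400 | current ambient |
| `gamma_star` | CO₂ compensation point | μmol mol⁻¹ | 42.75 | 25 °C literature value |
| `km` | effective Michaelis constant | μmol mol⁻¹ | 711 | 25 °C literature value |
| `diffusivity_ratio` | H₂O/CO₂ diffusivity | – | 1.6 | molecular diffusivities in air |
| `sif_scale` | SIF unit conversion | – | 1 | see below |

CO₂ quantities are treated as mole fractions; only differences and
ratios enter, so partial pressures in consistent units give identical
results. No temperature response of $\Gamma^*$, $K_m$ or
$\Phi_{PSIImax}$ is applied — the chain is used as a fixed-parameter
seasonal model, and users working across wide temperature ranges should
supply their own adjusted constants per run. The exact Ci, Ca,
$\Gamma^*$ and $K_m$ used in published field applications of this chain
are typically not reported; the defaults above are conventional 25 °C
C3 values, and every one is config-overridable (`load_config()`,
`write_config()`, or CLI flags).

**Units across the SIF–ETR relation.** SIF in mW m⁻² nm⁻¹ sr⁻¹ enters
ETR in μmol m⁻² s⁻¹ with no explicit radiometric-to-photon-flux
conversion: the conversion is absorbed into the proportionality, as is
conventional for this relation. For physically calibrated work the
`sif_scale` factor can carry an explicit conversion; it multiplies SIF
before the mechanism and defaults to 1 (the literal relation).

## Elasticities and sensitivity

Both PSII parameters enter only through the global constant
$C(\Phi, k_{DF}) = \Phi(1+k_{DF})/(1-\Phi)$, so

$$\frac{\partial \ln \mathrm{ETR}}{\partial \ln \Phi_{PSIImax}}
  = \frac{1}{1-\Phi_{PSIImax}} = 5.882 \text{ at } 0.83, \qquad
  \frac{\partial \ln \mathrm{ETR}}{\partial \ln k_{DF}}
  = \frac{k_{DF}}{1+k_{DF}} = 0.95 \text{ at } 19 .$$

`sensitivity_analysis()` runs the retrieval at ±10% one-at-a-time
perturbations of the two parameters. Because the perturbation is a
global multiplicative factor, the relative change is identical at every
timestamp and identical for Vcmax and gs — +10% on $k_{DF}$ multiplies
everything by exactly $21.9/20 = 1.095$, +10% on $\Phi_{PSIImax}$ by
$(0.913 \cdot 0.17)/(0.83 \cdot 0.087) \approx 2.149$. The report gives
relative changes (series-independent) rather than absolute trait
curves; the scientific conclusion — the retrieval is an order of
magnitude more sensitive to $\Phi_{PSIImax}$ than to $k_{DF}$ — is the
ordering of these factors, which `analytic_elasticities()` provides in
closed form as a cross-check on the perturbation machinery.

## The forward simulator

`simulate_season()` generates a synthetic growing season by running the
retrieval equations in reverse from a known truth: a lognormal-shaped
seasonal Vcmax trajectory (rise, broad early peak, long decline —
defaults peak 130 μmol m⁻² s⁻¹ at 30% of a 120-day season), smooth
seasonal arcs for PAR (350–500 W m⁻²), NIRv (0.10–0.40) and FPAR
(0.40–0.95), the exponential qL truth ($a = 0.9$, $b = -0.001$), and
multiplicative mean-one lognormal observation noise (default CV 5% on
SIF, 0 on the reflectance indices, seed 42). `generate_ql_pairs()`
likewise produces 40 (qL, PAR) pairs on an even 0–2000 W m⁻² grid with
additive Gaussian noise (sd 0.02).

Because the forward model is constructed as the exact inverse of the
retrieval, a zero-noise simulation must be recovered to machine
precision — the package's strongest internal consistency check — and
mean-one multiplicative noise leaves the retrieval asymptotically
unbiased.

What the simulator does **not** emulate: radiative transfer within the
canopy (qL and ε are imposed, not derived from structure), diurnal
cycles (daily values suffice to exercise the chain), weather-driven
PAR variability, instrument-specific SIF retrieval error structure, or
any violation of the model's own equations. Passing recovery tests
therefore demonstrates that the implementation inverts its stated
physics through realistic noise — not that the physics describes any
particular field canopy.

## Numerical choices

- **qL fit on the original scale.** Log-transforming qL would reweight
  errors toward small qL; the log-linear regression is used only to
  initialise the Levenberg–Marquardt optimiser (`minpack.lm::nlsLM`,
  iteration cap 200, ftol/ptol 1e-14). The optimised residual sum of
  squares is asserted never to exceed the initialiser's.
- **R² conventions.** Curve-fit R² is 1 − SSres/SStot on the original
  scale. Agreement R² in `evaluate()` is the squared Pearson
  correlation, reported together with the OLS slope/intercept of
  predictions on observations (the scatter-plot convention); the
  documentation flags that R² alone does not imply agreement.
- **Accuracy improvement** is defined on MAE,
  $100\,( \mathrm{MAE}_{base} - \mathrm{MAE}_{model})/\mathrm{MAE}_{base}$;
  defining it on RMSE would give a different number, so the choice is
  stated explicitly wherever it is reported.
- **Degenerate inputs.** Records with FPAR outside (0, 1] are rejected
  at parse time (drop-and-log, no imputation); records with NIRv = 0
  (escape probability 0, ETR undefined) are skipped with a message
  during retrieval rather than propagating NaN; qL predictions above 1
  are clamped with a warning; negative linear-baseline predictions are
  floored at 0. Seasonal series tolerate gaps, so skipping is safer
  than imputing.
- **Time** is (year, day-of-year) integers — seasonal retrievals need
  no intra-day resolution — with an optional fractional `hour` column
  carried through untouched. A single simulated season is therefore
  capped at 366 days; long-run properties (e.g. asymptotic
  unbiasedness over ~1000 days) are checked by pooling several
  synthetic years.
- **Determinism.** Every stochastic operation takes an explicit seed
  and is run under a scoped RNG (`withr::with_seed`), so simulations
  are bit-reproducible and never disturb the caller's RNG state. Test
  and example problem sizes (120-day seasons, 40 qL pairs, ~1000-day
  pooled bias checks) keep the whole suite fast while leaving the
  statistical checks well-powered.

## Known limitations

- The qL–PAR law is empirical; qL also varies with canopy depth and
  stress, which a single exponential in PAR cannot capture.
- ε ≈ NIRv/FPAR is an approximation to a radiative-transfer quantity;
  no uncertainty is propagated through it.
- Fixed $\Phi_{PSIImax}$ ignores photoinhibition; given the 5.9
  elasticity, stressed conditions will bias all three traits strongly.
- The co-limitation assumption $A_c = A_j$ holds at typical midday
  operating points; under strong light or CO₂ limitation the retrieved
  Vcmax is an effective, not biochemical, quantity.
- The linear baseline is a single pooled OLS with intercept; no
  regularised or multivariate baselines are provided.
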