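# otoFMR

Field metabolic rate (FMR) — the total aerobic energy expenditure of a
free-ranging animal — is nearly unmeasurable in wild fish: doubly labelled
water fails in water-breathers, and telemetry only proxies activity. The
carbon isotope composition of otolith aragonite offers a direct,
retrospective route. Otolith carbon mixes two isotopically distinct pools —
ambient dissolved inorganic carbon (DIC, heavy) and respired dietary carbon
(light) — so the proportion of metabolically derived carbon,

```
M_oto = (δ13C_oto − δ13C_DIC) / (δ13C_diet − δ13C_DIC) + ε ,
```

rises with oxygen consumption. Because the proportion is bounded, its
relationship with oxygen consumption saturates:

```
M_oto = C (1 − exp(−k · O2)),     O2 = −ln(1 − M_oto/C) / k ,
```

with asymptote `C` and rate constant `k` calibrated on reared fish
(cod-like values: C ≈ 0.243, k ≈ 8.8×10⁻³ per mg O2 kg⁻¹ h⁻¹). `otoFMR`
implements the full pipeline for ecophysiologists and otolith
biogeochemists:

* **Mixing model** with Monte Carlo and delta-method uncertainty
  (`compute_moto`, `propagate_moto`, `moto_sd_delta_method`)
* **Oxygen-isotope thermometry** (`fit_thermometry`, `predict_temperature`)
* **Metabolic models**: Boltzmann–Arrhenius SMR, slope-only B0 fits,
  SMR→RMR scaling, swim-tunnel SMR extrapolation (`mte_model`, `fit_B0`,
  `smr_to_rmr`, `smr_from_swim`)
* **Calibration** with errors-in-both-variables Monte Carlo ensembles and
  censored inversion to FMR (`fit_calibration`, `moto_to_fmr`)
* **Power-budget validation tests** against literature bounds
  (`test1_budget`, `test2_activity`, `test3_scope`, `run_budget_suite`)
* **AIC-profiled allometric exponents** across species and through
  ontogeny (`fit_alpha`, `fit_alpha_ontogeny`)
* **Power analysis** for study design (`moto_effect_size`, `min_samples`,
  `power_curve`)
* **Synthetic-data generators** with hidden truth tables for end-to-end
  validation (`simulate_rearing`, `simulate_wild_population`,
  `simulate_species_compilation`)

Units throughout: δ values in ‰ vs VPDB, mass in g, temperature in °C
(Kelvin only inside Arrhenius terms), oxygen consumption in
mg O2 kg⁻¹ h⁻¹.

## Worked example

From one otolith measurement to an FMR estimate, then a design
calculation:

```r
library(otoFMR)

# 4 °C reared-cod group: otolith −2.23 ‰, two water samplings, diet −19.96 ‰
em <- endmembers(d13C_DIC = c(-0.15, -0.22), d13C_diet = -19.96)
m  <- propagate_moto(-2.23, em, d13C_oto_sd = 0.17, n_draws = 10000, seed = 1)
m
#> M_oto = 0.1037 (MC sd 0.0101, n = 10000 draws)

cv  <- calibration_curve(C = 0.243, k = 0.0088, se_C = 0.035, se_k = 0.00138)
fmr <- moto_to_fmr(m, cv, n_draws = 10000, seed = 2)
fmr
#> FMR = 68.4 mg O2 kg-1 h-1 (MC sd 22.58, 0.0% censored)

# samples per population to resolve a 2 °C metabolic contrast at 80% power
min_samples(moto_effect_size(delta_T = 2), sd = 0.0195)
#> [1] 32
```

About 10% of this fish's otolith carbon is metabolic; inverting the
calibration puts its routine oxygen consumption near 68 mg O2 kg⁻¹ h⁻¹,
with the curve's own uncertainty dominating the spread. Resolving a 2 °C
thermal contrast between two populations (ΔM_oto = 0.014) needs 32
otoliths per population.

Recovering the calibration from a synthetic rearing experiment (63 fish,
known truth C = 0.243, k = 0.0088):

```r
d   <- rearing_design(n_per_group = c(11, 15, 19, 18), seed = 42)
sim <- simulate_rearing(d)
fit <- fit_calibration(sim$truth$rmr,
                       compute_moto(sim$samples$d13C_oto, d$ends),
                       moto_sd = moto_sd_delta_method(sim$samples$d13C_oto, d$ends),
                       o2_sd = 0.054 * sim$truth$rmr, n_mc = 1000, seed = 43)
fit
#> Saturating calibration: M = C(1 - exp(-k * O2))
#>   C = 0.2416 (se 0.01507), k = 0.009058 (se 0.0008775), n = 63
#>   MC ensemble: 1000 fits, sd(C) = 0.01734, sd(k) = 0.001044
```

Both truth values sit well inside one ensemble SD.

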