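---
title: "Estimating field metabolic rate from otolith carbon isotopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating field metabolic rate from otolith carbon isotopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoFMR)
```

## The proxy in one paragraph

Carbon in fish blood — and therefore in the aragonite of the otolith, which
precipitates from the endolymph — comes from two isotopically distinct
sources: dissolved inorganic carbon (DIC) in the ambient water (heavy,
$\delta^{13}$C typically above $-1$‰) and metabolic carbon respired from
food (light, typically below $-19$‰). As oxygen consumption rises, the
metabolic fraction of blood carbonate rises, so the otolith
$\delta^{13}$C value falls. Because otolith aragonite is metabolically
inert once deposited, each sampled increment is a time-integrated archive
of the fish's field metabolic rate (FMR) at the time it grew. `otoFMR`
turns that archive into oxygen-consumption estimates with propagated
uncertainty, and provides the validation and design tools that a study
using the proxy needs.

## Stage 1: the two-endmember mixing model

The proportion of metabolically derived carbon in otolith aragonite is

$$M_{oto} = \frac{\delta^{13}C_{oto} - \delta^{13}C_{DIC}}
                 {\delta^{13}C_{diet} - \delta^{13}C_{DIC}} + \varepsilon,$$

implemented in `compute_moto()`. The net fractionation term $\varepsilon$
is applied additively to the proportion and defaults to 0, the value
supported by freshwater-fish validation work; it is configurable in
`endmembers()`. Repeated water samplings may be supplied as a vector for
the DIC endmember; they are averaged and their spread informs the DIC SD.
Default endmember SDs are 0.03‰ (DIC) and 0.86‰ (diet); the default otolith
repeatability is 0.17‰, the intra-otolith standard deviation of repeated
micromill samples.

Estimates outside $[0, 1]$ are *flagged, never clipped* at this stage:
an out-of-range $M_{oto}$ is diagnostic of endmember misspecification and
clipping would hide it. Censoring happens only at calibration inversion.

`propagate_moto()` draws the three inputs independently from Gaussians
(measurement error is instrument-level and shared structure is absorbed in
the means) and summarises $M_{oto}$ over 10,000 draws by default.
`moto_sd_delta_method()` provides the first-order analytic SD used as an
independent cross-check; at the reared-cod group means the two agree within
a few percent, and the average Monte Carlo SD is about 0.010.

## Stage 2: oxygen-isotope thermometry

Experienced temperature is reconstructed from otolith $\delta^{18}$O by a
linear model fitted with temperature on the left-hand side
(`fit_thermometry()`), matching how the model is used for prediction. For
wild fish, published aragonite fractionation coefficients are supplied via
`thermometry_model()`; none are hard-coded, because transcription from the
original source — with its salinity and water-$\delta^{18}$O assumptions —
is the user's responsibility. Water $\delta^{18}$O is absorbed into the
fitted intercept for tank experiments.

Monte Carlo prediction (`predict_temperature()`) resamples both the
coefficient uncertainty and the residual scatter; the two sources are
separately switchable because study designs differ in which one dominates,
and the correct combination for a given application is a judgement call we
leave exposed rather than fix.

## Stage 3: metabolic models

Standard metabolic rate follows the Boltzmann–Arrhenius form of the
metabolic theory of ecology (MTE):

$$\mathrm{SMR} = B_0 \, m^{\alpha} \, e^{-E/(k_B T)},$$

with $E = 0.65$ eV, $k_B = 8.62\times10^{-5}$ eV K$^{-1}$, and the
mass-specific exponent convention ($\alpha = -0.25$ theoretical, $-0.21$
empirical for fishes; whole-organism exponent $= \alpha + 1$). Every
reported exponent carries an explicit convention tag because the
mass-specific/whole-organism distinction is a recurrent source of
confusion. With the constants fixed, $B_0$ is a slope-only regression
through the origin on the composite predictor
$m^{\alpha} e^{-E/(k_B T)}$ (`fit_B0()`); its $R^2$ uses the
origin-constrained convention $1 - \mathrm{RSS}/\sum y^2$.

**Units matter for $B_0$.** The package works in grams and
mg O$_2$ kg$^{-1}$ h$^{-1}$ throughout. A $B_0$ fitted with mass in kg
rescales by $1000^{-\alpha}$ when mass moves to grams; the cod-like default
used by the synthetic generators, $8.04\times10^{13}$, is the
kg-convention value $1.43\times10^{13}$ converted to grams at
$\alpha=-0.25$. A fitted $B_0$ should never be treated as portable across
conventions.

Routine metabolic rate of fed fish is a Gaussian multiple of SMR,
$1.55 \pm 0.0832$ (`smr_to_rmr()`). Swim-tunnel SMR is extracted by
fitting $MO_2 = a e^{b \cdot speed}$ and extrapolating to zero speed
(`smr_from_swim()`); the default fit is OLS on $\log MO_2$ — the natural
reading of "an exponential model fitted by ordinary least squares" — with
direct nonlinear least squares available as a cross-check option.
Behavioural exclusion flags on respirometry loops are honoured as data and
never re-derived.

## Stage 4: the saturating calibration and its inversion

$M_{oto}$ is bounded below by 0 and above by the blood-chemistry ceiling
$C$, so its relationship with oxygen consumption is an increasing
exponential saturation:

$$M_{oto} = C\left(1 - e^{-k \cdot O_2}\right).$$

`fit_calibration()` fits $(C, k)$ by bounded Levenberg–Marquardt NLS
(starting values $C = 1.2\max(M)$ capped below 1, $k = 1/\overline{O_2}$ —
robust for saturating curves). Uncertainty in *both* variables is
propagated by Monte Carlo re-draw and refit: each repeat perturbs the
$O_2$ and $M_{oto}$ values within their SDs and refits, and the ensemble
of $(C,k)$ pairs carries the joint, correlated uncertainty downstream.
Both the central NLS estimate and the ensemble mean are reported, since
either is a defensible point estimate. On reared-cod-like data the fit
gives $C \approx 0.243$ and $k \approx 8.8\times10^{-3}$
(mg O$_2$ kg$^{-1}$ h$^{-1}$)$^{-1}$.

The inversion (`moto_to_fmr()`) is the exact inverse
$O_2 = -\ln(1 - M/C)/k$ on $(0, C)$; for example $M = 0.10$ with the
coefficients above gives $\approx 60.3$ mg O$_2$ kg$^{-1}$ h$^{-1}$.
Monte Carlo draws pair an $M$ draw with a $(C,k)$ ensemble member; draws
with $M \ge C$ are *censored* — counted and excluded, never truncated to
$C - \epsilon$ — because values above a species' calibrated ceiling are
real signals (deep-sea species exceed the cod bound) and silently
truncating them would manufacture precision. An estimate with more than
half its draws censored is marked unreliable.

## Validation: the power-budget tests

FMR decomposes as SMR + SDA (specific dynamic action, the postprandial
rise) + activity. Three checks, with literature bounds collected in
`literature_bounds()`:

1. **Budget** (`test1_budget()`): even at the maximal SDA fraction (0.4 of
   assimilated energy), FMR must exceed SMR + SDA, i.e.
   $0.6\,\mathrm{FMR} > \mathrm{SMR}$.
2. **Activity** (`test2_activity()`): with a juvenile-average SDA of
   0.12·FMR, activity/SMR must fall in the published 0.3–3.9 range.
3. **Scope** (`test3_scope()`): the factorial scope FMR/SMR must not
   exceed the maximum-metabolic-rate scope (2.3–3.5).

Interval endpoints are treated as inclusive — the sources report ranges
without open/closed qualification, and excluding an endpoint would fail a
fish for matching a published value exactly. `run_budget_suite()` chains
the full pipeline per fish and reports both point-estimate flags and the
Monte Carlo fraction of draws passing each test, because near a bound the
point flag alone overstates certainty.

## Allometry: AIC-profiled exponent estimation

Substituting the MTE model into the calibration gives

$$M_{oto} = C\left(1 - e^{-k B_0 m^{\alpha} e^{-E/(k_B T)}}\right),$$

with $(C, k)$ carried fixed from the calibration. For each candidate
$\alpha$ on a grid ($-1$ to $0.2$ in steps of 0.005, covering the
metabolic-level-boundaries range of whole-organism exponents 2/3–1 with
margin for low-activity outliers), the single free parameter $B_0$ is
profiled out by 1-D least squares in $\log B_0$ (`optimize()` around a
moment-matching start). The profile AIC is $n\ln(\mathrm{RSS}/n) + 2p$
with $p = 1$; the argmin is refined by golden-section search between its
neighbouring grid points.

**Support-interval convention.** The reported 2-AIC support interval
compares each fixed-$\alpha$ model (one estimated parameter, $B_0$) with
the *selected* model, which estimated both $\alpha$ and $B_0$ from the
data (two parameters). Under the standard 2-AIC-unit rule this retains
$\alpha$ values with $n\ln(\mathrm{RSS}_\alpha/\mathrm{RSS}_{min}) \le 4$,
asymptotically a ≈95% likelihood interval. Ignoring the extra estimated
parameter would shrink this to a ≈84% interval
($P(\chi^2_1 \le 2) = 0.843$) and systematically understate the exponent's
uncertainty; the two-parameter accounting is the honest one for a profile
whose minimiser was itself chosen by the data.

`fit_alpha_ontogeny()` applies the same machinery within species along
ontogenetic (increment-by-increment) series; temperature enters per
record, so thermal habitat shifts during ontogeny are corrected before the
mass trend is attributed to $\alpha$. Rows with $M_{oto} \ge C$ are
excluded with a warning under the censoring policy. A degenerate design
(no mass variation) yields a flat profile and an explicit flag, since
$B_0$ then absorbs any $\alpha$.

## Study design: power analysis

`moto_effect_size()` converts a temperature contrast to an expected
$M_{oto}$ difference, either through the observed linear slope (0.007 per
°C in reared cod) or through the calibration curve given a baseline and a
proportional change in oxygen consumption. `min_samples()` returns the
smallest per-group $n$ for a two-sample, two-sided t-test at 80% power and
$\alpha = 0.05$ — analytically via the exact noncentral-$t$ calculation,
or by simulation as an assumption-light cross-check (the two agree within
±1).

The reference per-group $M_{oto}$ SD shipped in the documentation, 0.0195,
is *back-derived* from the published design calculation for this proxy
(32 samples per population to resolve a 2 °C contrast, i.e.
$\Delta M = 0.014$, at 80% power): it is the SD that design implies, and
it is consistent with the reported among-individual variability (group SDs
up to 0.024, "less than 0.025"). Users with their own data should supply
their observed group SDs instead.

## The synthetic-data generators

The generators exist so that every inference path can be tested against a
known truth. `rearing_design()`/`simulate_rearing()` emulate a
four-temperature (4/7/10/14 °C) rearing experiment: masses log-uniform in
94–783 g (only ranges are knowable, and log-uniform spreads them evenly
across the allometric axis), SMR from the MTE truth, RMR as a Gaussian
multiple (1.55 ± 0.0832) of SMR, $M_{oto}$ from the calibration truth
($C = 0.243$, $k = 0.0088$), and observables generated by inverting the
mixing model and the thermometry line
($T = 21.0 - 4.85\,\delta^{18}O$, the OLS line through the four group
means) with independent Gaussian noise (0.17‰ on $\delta^{13}$C, 0.28‰ on
$\delta^{18}$O). All noise is Gaussian and independent across fish and
isotopes; tank-level random effects are *not* modelled. Truth tables are
returned in a separate schema from observables, and inference code never
reads them.

`wild_design()` adds age-structured trajectories (von Bertalanffy growth
cubed for mass, an arbitrary temperature-at-age rule, FMR as a fixed
factorial scope times SMR), one multiplicative size deviation per fish so
masses stay non-decreasing with age. `species_design()` draws one row per
species (default 76) with log-uniform masses from 1 g to 100 kg and
temperatures uniform on 2–28 °C; its default residual SD on $M_{oto}$,
0.03, reproduces roughly 40% unexplained among-species variance at the
observed spread of ≈0.05 — the level reported for real compilations.

What the generators deliberately do **not** emulate: otolith
growth-increment geometry and drilling averaging (beyond a per-sample
integration window), spatial $\delta^{13}C_{DIC}$ fields, tank effects,
non-Gaussian error families, and species-specific calibration curves.
Passing tests on synthetic data therefore demonstrate the *inference
machinery* is correct and calibrated, not that real data meet these
assumptions.

## Numerical choices and degenerate inputs

* Calibration NLS: bounds $C \in (0, 5]$ (values above 1 are flagged, not
  prevented, so misspecification is visible), $k > 0$; failed Monte Carlo
  refits are dropped and counted, with a warning above 5%.
* Inversion guards: draws with $M \le 0$ or $M \ge C$ are censored;
  censoring above 50% marks the estimate unreliable.
* $B_0$ profiling is in $\log B_0$ with a ±12 bracket around a
  moment-matching start (inverting the calibration at clamped $M$).
* Equal endmembers, fewer than two temperature levels, non-positive MO$_2$,
  zero SMR in a scope, and empty input files are hard errors with
  actionable messages; degenerate mass ranges yield flags, not errors.
* Problem sizes in the shipped tests: 200 replicate rearing experiments
  (63 fish each, 150-fit ensembles) for calibration coverage and 100
  replicate 76-species compilations for exponent coverage — sizes at which
  the binomial error of a coverage estimate is a few percent.

## Known limitations

The calibration is species-specific (cod-derived here); transferring it
across species is an open scientific question, and the package only
*mechanically* supports substituting another fitted curve. The DIC
endmember is assumed spatially homogeneous. SDA enters the budget tests as
a fixed fraction, not a measured quantity. The thermometry line absorbs
water $\delta^{18}$O into its intercept, which is only valid where water
composition is stable.
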