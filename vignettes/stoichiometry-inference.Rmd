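---
title: "Inferring cotransporter stoichiometry from voltage-clamp and tracer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cotransporter stoichiometry from voltage-clamp and tracer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotransport)
```

## The problem

Sodium- and chloride-coupled transporters of the SLC6 family move a fixed
number of ions per substrate molecule, and that number determines how much
uphill transport the electrochemical gradients can power. For the glycine
transporters, GlyT1 couples 2 Na⁺ : 1 Cl⁻ : 1 glycine and GlyT2 couples
3 Na⁺ : 1 Cl⁻ : 1 glycine; losing or gaining one coupled sodium changes
both the net charge moved per cycle and the concentrating capacity of the
transporter. This package implements the quantitative chain by which that
stoichiometry is read out of two-electrode voltage-clamp (TEVC) recordings
in *Xenopus* oocytes and radiotracer uptake assays in transfected cells.

## The thermodynamic model

Transport is treated purely thermodynamically: at the reversal potential
$E_T$ the free energy of one complete cycle is zero, so for $n_{Na}$
sodium ions, $n_{Cl}$ chloride ions and one zwitterionic substrate
molecule per cycle,

$$E_T = \frac{2.3\,R\,T}{z_T F}\,
\log_{10}\!\frac{[\mathrm{Na}]_o^{n_{Na}}\,[\mathrm{Cl}]_o^{n_{Cl}}\,[S]_o}
{[\mathrm{Na}]_i^{n_{Na}}\,[\mathrm{Cl}]_i^{n_{Cl}}\,[S]_i},
\qquad z_T = n_{Na} - n_{Cl}.$$

No kinetic (rate-constant or alternating-access) model is implied: the
model predicts only where the current reverses, not its shape. Three
consequences drive the analyses:

* the slope of $E_T$ against $\log_{10}[\mathrm{Na}^+]_o$ is
  $2.3\,R\,T\,n_{Na}/(z_T F)$ per decade — `slope_per_decade()`;
* a measured slope inverts to $n_{Na}$ once $z_T$ is known —
  `infer_n_na()`;
* $z_T$ itself is measurable as the charge-to-flux ratio, moles of
  integrated charge per mole of accumulated substrate —
  `charge_to_flux()`.

At 18 °C (the oocyte recording temperature) the predictions are 86.55
mV/decade for 3Na:1Cl ($z_T = 2$) and 115.41 mV/decade for 2Na:1Cl
($z_T = 1$):

```{r slopes}
slope_per_decade(stoichiometry(3, 1), temperature_c = 18)
slope_per_decade(stoichiometry(2, 1), temperature_c = 18)
```

### Constants and units

`phys_constants()` uses $R = 8.314$ J mol⁻¹ K⁻¹, $F = 96485$ C mol⁻¹ and
a decade prefactor of 2.3 — the rounding conventional in the
electrophysiology literature, rather than $\ln 10 = 2.303$. The choice
moves the slope predictions by only ~0.1%, and the constants are
configurable so either rounding can be reproduced exactly. Concentrations
are in mM (only ratios enter the model), potentials in mV, temperature in
°C at the interface and kelvin internally. Temperature defaults to 18 °C,
the oocyte bath; use 37 °C for cultured-cell uptake work. Zero
concentrations are rejected outright — the model is logarithmic, and a
nominally ion-free solution should be represented by its actual residual
concentration.

Intracellular concentrations in injected oocytes are rarely known; the
`ion_conditions()` defaults (Na⁺ 10 mM, Cl⁻ 40 mM, substrate 10 mM) are
documented assumptions, not measurements, and only shift the intercept of
the reversal series, never the slope on which the inference rests.

## Trace and I/V analysis

`integrate_charge()` uses trapezoidal integration of the
baseline-corrected current over the application window. The baseline is
the mean current in the 5 s before the application window — anchored to
the application, not to the integration window, so charge is additive
over sub-windows. Reversal potentials on discrete I/V grids are obtained
by linear interpolation between the unique sign-change bracket
(`estimate_erev()`); a curve that never crosses zero in the tested range
(the wild-type behavior under a full driving force) raises a
"non-reversing" error rather than extrapolating. The rectification degree
follows the standard three-point rule: the OLS slope through the three
most hyperpolarized points divided by the slope through the three most
depolarized ones; it is 1 for any affine curve and invariant to uniform
current scaling. Tracer counts convert at 2.22 × 10¹² dpm/Ci.

## Saturation kinetics

`fit_hill()` fits $v = V_{max} C^n / (EC_{50}^n + C^n)$ by unweighted
Levenberg–Marquardt least squares on the raw replicate rates (replicates
enter individually, not as means; no weighting scheme is assumed).
Initialization is deterministic: $V_{max}$ starts at the largest
per-concentration mean rate, $EC_{50}$ at the concentration whose mean
rate is nearest half-maximum, and the exponent is multi-started over
$\{0.5, 1, 2, 3\}$ with best-SSE selection; starts converging to
non-positive parameters are discarded. `fit_mm()` is the same engine with
$n \equiv 1$, so the Hill SSE can never exceed the Michaelis–Menten SSE
on the same data. Fits on data whose largest mean rate is below twice the
rate at the lowest concentration are flagged (`saturation_warning`): the
curve top is then poorly constrained. Background uptake by
mock-transfected cells is removed per concentration before fitting
(`subtract_background()`); corrected rates driven negative are clipped to
zero and counted rather than discarded, which keeps the concentration
grids of construct and mock matched.

`transport_efficiency()` reports $V_{max}/K_m$ with a first-order
(delta-method) standard error. This is the ratio of the fitted means;
published tables that average per-experiment ratios can differ from it,
and the package makes no attempt to guess such averaging.

## The synthetic-experiment generator

The generators exist so that every stage of the analysis chain can be
exercised, with known ground truth, at the scales of real oocyte data:
currents of tens of nA at −150 mV, Na⁺ grids up to 150 mM, the −150 to
+30 mV step-20 protocol, a 1-min tracer application at 0.4 Ci/mmol, and
per-oocyte reversal-potential noise of a few mV.

* **I/V curves** follow $I(V) = g\,z_T\,(V - E_T)\,\sigma(V)$ with
  $\sigma(V) = 1/(1 + e^{(V - V_0)/k})$. The linear driving force times a
  sigmoidal factor is an artifact choice — the thermodynamic model
  dictates no I/V shape — selected as the simplest form with an exact
  zero at $E_T$ and tunable inward rectification. Defaults $g = 0.3$
  nA/mV, $V_0 = -30$ mV, $k = 30$ mV give wild-type-like inward
  rectification and ≈ −70 nA at −150 mV for a $z_T = 2$ transporter;
  $k = \infty$ disables rectification. Because $\sigma$ curves the limbs,
  linear interpolation of the noiseless 20-mV grid recovers an off-grid
  $E_T$ to about 2 mV (a tenth of the step), and exactly when $E_T$ falls
  on a grid point.
* **Reversal series** add Gaussian noise (default scenario: SD 5 mV, 8
  oocytes, five Na⁺ levels from 20 to 100 mM) to the thermodynamic $E_T$
  per oocyte.
* **Charge/flux experiments** move $N = \text{rate} \times \text{duration}$
  moles, with evoked current $z_T F N/\text{duration}$ and tracer counts
  $N \times 10^3 \times \text{SA} \times 2.22\times10^{12}$ dpm over
  background, sampled at 1 kHz; the noiseless chain returns $z_T$ to
  numerical precision by construction, which is the end-to-end identity
  the tests rely on.
* **Uptake datasets** draw $v = \text{model}(C)\,(1 + \varepsilon)$,
  $\varepsilon \sim N(0, \text{CV})$, with the mock background added to
  the sample rates so that subtraction restores the clean curve.

Seeding is explicit and hierarchical: every generator requires a seed, and
per-oocyte/replicate streams are derived with a fixed prime stride, so
adding replicates never perturbs earlier ones and identical specs yield
identical bytes.

What the generator does *not* emulate — endogenous oocyte conductances,
leak and capacitive transients, electrode series resistance, tracer
counting statistics, day-to-day expression variability — bounds what
passing tests show: they validate the analysis chain's correctness and
statistical behavior under its own assumptions, not its robustness to
every artifact of real recordings. Published charge-to-flux measurements
scatter around the integer net charge (values both above 2 and below 1
are reported for the two coupling modes); the package reports ratios
without any leak or bias correction, since the split between leak and
noise is not identifiable from the ratio alone.

## End-to-end pipeline

`run_pipeline()` takes a YAML/JSON (or in-memory) configuration naming,
per construct, an assumed stoichiometry and either input CSV files or
simulation parameters, and produces a stoichiometry report: Hill and
Michaelis–Menten parameters, reversal slope with inferred $n_{Na}$,
charge-to-flux ratio ± SEM, rectification degree, and provenance (seed,
config hash, inputs). Reports are byte-deterministic for a fixed config.

```{r pipeline}
cfg <- list(
  seed = 1, temperature_c = 18,
  conditions = list(na_o = 100, cl_o = 40, gly_o = 1),
  constructs = list(
    glyt2_like = list(
      stoichiometry = list(n_na = 3, n_cl = 1),
      simulate = list(
        erev = list(na_o_list = c(20, 40, 60, 80, 100), n_oocytes = 4),
        charge_flux = list(transport_rate = 1e-13, n_repeats = 2),
        iv = list(na_o = 20)))))
run_pipeline(cfg)
```

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately compact
problem sizes — 8 simulated oocytes over five Na⁺ levels, 100-repeat
Monte Carlo for the noisy charge-to-flux mean, 60-s traces at 1 kHz,
12-point uptake curves with 3 replicates — chosen to match the scale of
the corresponding laboratory experiments while keeping every recovery
property (slopes within two standard errors, EC₅₀ within 15% under 5%
rate noise, charge-to-flux within 2% under 2 nA current noise) clearly
resolvable. Degenerate inputs fail loudly: electroneutral stoichiometries
have no reversal potential, non-reversing I/V curves raise rather than
extrapolate, flat uptake data are unidentifiable, and mismatched
concentration or potential grids are reported with the offending values.

## Limitations

The thermodynamic model predicts equilibrium only; nothing here infers
turnover rates or transport currents away from reversal. The Hill
coefficient is reported as fitted and is a lower bound on the number of
cooperating sodium sites, not a count. Charge-to-flux ratios assume all
evoked charge is carried by coupled transport — uncoupled conductances
bias the ratio upward and are not corrected. Group-level hypothesis
testing between constructs is out of scope; the report is descriptive.
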