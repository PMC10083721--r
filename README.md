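# erleak

Kinetic analysis of thapsigargin (TG)-induced Ca²⁺ mobilisation in
live-cell imaging.

When TG blocks the SERCA pump, the passive ER Ca²⁺ leak is unmasked: ER
Ca²⁺ runs down while a transient Ca²⁺ surge appears in the cytosol and is
removed again by plasma-membrane clearance. This package is for
experimenters who record such responses with ratiometric sensors (FURA-2
for the cytosol, D1ER for the ER lumen) and want rate constants and
fluxes rather than raw traces: the ER leak rate k_leak, the ER depletion
rate k_depl, the cytosolic clearance rate k_clear, the store-operated
Ca²⁺ entry (SOCE) rate, and the driving luminal pool b[Ca²⁺]_lER.

At its core is the one-compartment model of the baseline-subtracted
cytosolic transient, the Bateman equation:

```
Δ[Ca²⁺]_cyt(t) = b[Ca²⁺]_lER · k_leak/(k_clear − k_leak) · (e^(−k_leak·t) − e^(−k_clear·t))
```

with closed-form peak time `ln(k_clear/k_leak)/(k_clear − k_leak)`, AUC
`b[Ca²⁺]_lER/k_clear`, and the equal-rate limit `b·k·t·e^(−k·t)` handled
analytically. `fit_bateman()` estimates `(b_lER, k_leak)` by
Levenberg–Marquardt least squares with `k_clear` fixed to a separately
measured clearance value (fitting all three rates is supported, with the
flip-flop identifiability hazard handled and flagged). Around it:

* `ratio_to_concentration()` / `concentration_to_ratio()` — the standard
  ratiometric calibration pair `C = K·(R − R_min)/(R_max − R)`;
* `transient_metrics()`, `smooth_derivative()`, `find_inflection()`,
  `soce_slope()`, `percent_depletion()` — model-free trace analysis;
* `fit_exponential_decay()`, `fit_depletion_rate()` — first-order rate
  estimation for clearance and ER depletion;
* `phase_diagram()` — amplification/attenuation sweeps over k_leak;
* `er_volume_fraction()` — ER morphometry arithmetic
  (`volume fraction = area fraction^(3/2)`);
* `generate_experiment()` / `fixture_suite()` — a seeded synthetic-data
  generator for paired cytosolic/ER traces;
* `run_analysis()` — the full pipeline from a YAML run-config to a
  unit-tagged report.

## Worked example

Simulate a dual-sensor TG experiment in Ca²⁺-free bath (control kinetics,
10-s sampling, realistic noise), then recover the kinetics:

```r
library(erleak)

tru <- ground_truth(bateman_params(2.40, 14.55e-3, 28.34e-3), k_depl = 6.28e-3)
ex  <- generate_experiment(protocol_spec("tg_zero_ca", seed = 42), tru)

transient_metrics(ex$cyt)
#> <transient_metrics> baseline 0.07 uM | peak amplitude 0.6482 uM |
#>   t_peak 50 s | AUC 79.34 uM*s | duration 270 s

fit_bateman(ex$cyt, k_clear = 28.34e-3)
#> One-compartment (Bateman) Ca2+ transient fit
#>   b_lER  = 2.30652 uM
#>   k_leak = 0.0157012 s^-1 (tau = 63.69 s)
#>   k_clear = 0.02834 s^-1 (tau = 35.29 s) [fixed]
#>   rmse = 0.0229 uM on 55 samples

fit_depletion_rate(ex$er)
#> <depletion_fit> k_depl = 0.00569659 s^-1 (tau_depl = 175.544 s),
#>   r^2 = 0.9493, n = 45, window [150, 600] s
```

Reading these numbers: the cytosolic transient peaks at 0.65 µM above a
63-nM baseline about 50 s after TG; the fitted leak rate (15.7e-3 s⁻¹,
true value 14.55e-3) is roughly 2.5× the ER depletion rate (5.7e-3 s⁻¹,
true 6.28e-3) — the leak seen by the cytosol is faster than the bulk ER
run-down. Multiplying k_leak by the basal ER level gives the leak flux:

```r
first_order_flux(0.0157, estimate_baseline(ex$er))
#> J_leak = 5.85 uM/s
```

i.e. an ER Ca²⁺ leak in the range of a few µM/s at a basal ER Ca²⁺ of
~370 µM.

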