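---
title: "Kinetic analysis of thapsigargin-induced Ca2+ mobilisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of thapsigargin-induced Ca2+ mobilisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erleak)
```

## The experiment this package analyses

Thapsigargin (TG) irreversibly inhibits the SERCA pump. Applied to cells in
a Ca2+-free bath, it stops the re-uptake of Ca2+ into the endoplasmic
reticulum (ER) and thereby *unmasks* the passive ER Ca2+ leak: the leaked
Ca2+ accumulates transiently in the cytosol before plasma-membrane
clearance (PMCA/NCX) removes it. A cytosolic ratiometric dye (FURA-2,
F340/F380) and a FRET-based luminal sensor (D1ER, F_Citrine/F_CFP) report
the two compartments. The package turns such paired traces into rate
constants and fluxes:

* the **clearance rate** `k_clear` (s^-1), from the exponential decay of
  cytosolic Ca2+ after Ca2+ entry is abruptly interrupted with EGTA;
* the **ER depletion rate** `k_depl` (s^-1), from the first-order relation
  between -d[Ca2+]_ER/dt and [Ca2+]_ER after full SERCA blockade;
* the **ER leak rate** `k_leak` (s^-1) and the leak-driving luminal pool
  `b_lER` (uM), from a one-compartment (Bateman) fit to the cytosolic
  transient;
* the empirical **SOCE influx** (nM/s), as the initial slope after Ca2+
  re-addition.

Canonical units are micromolar and seconds everywhere inside the package;
nanomolar appears only at I/O boundaries with explicit unit tags.

## The one-compartment model

With external Ca2+ chelated, the cytosolic balance reduces to a first-order
source (the ER leak, driven by a luminal pool `b_lER` decaying at `k_leak`)
and a first-order sink (clearance at `k_clear`):

$$\frac{d[\mathrm{Ca}^{2+}]_{cyt}}{dt}
  = b_{lER}\,k_{leak}\,e^{-k_{leak} t} - k_{clear}\,[\mathrm{Ca}^{2+}]_{cyt}$$

whose solution for the baseline-subtracted transient is the Bateman
equation, familiar from one-compartment pharmacokinetics with first-order
absorption and elimination:

$$\Delta[\mathrm{Ca}^{2+}]_{cyt}(t)
  = b_{lER}\,\frac{k_{leak}}{k_{clear}-k_{leak}}
    \left(e^{-k_{leak}t} - e^{-k_{clear}t}\right)$$

`bateman_transient()` evaluates it, `bateman_components()` exposes the
single terms, and `bateman_analytics()` gives the closed forms

* `t_peak = log(k_clear/k_leak) / (k_clear - k_leak)`,
* `AUC = b_lER / k_clear`,
* `gain = k_leak / (k_clear - k_leak)`.

Model assumptions worth keeping in mind: both fluxes are strictly first
order; cytosolic buffering is absorbed into the effective rates; `b_lER`
is a *fit parameter* on the uM scale and is deliberately not equated with
the measured bulk ER Ca2+ level (hundreds of uM, dominated by luminal
buffers) — the package imposes no link between the two.

### Identifiability (flip-flop)

The curve determines the two rates only as an unordered pair: exchanging
`k_leak` and `k_clear` while rescaling the pool so that `b_lER * k_leak`
stays fixed reproduces the identical time course. `fit_bateman()` therefore
fixes `k_clear` by default to the value measured separately with the
clearance assay, fitting only `(b_lER, k_leak)`; when all three parameters
are freed, the solver keeps `k_leak <= k_clear` unless the caller opts into
the flip-flop search, and the summary flags the hazard.

### Numerical choices

* **Equal-rate degeneracy.** When the relative rate separation falls below
  1e-6, evaluation switches to the analytic limit
  `b_lER * k * t * exp(-k t)` with `k` the mean rate; below that threshold
  the cancellation error of the difference-of-exponentials exceeds the
  limit-form error. Tests assert continuity across the switch to within
  1e-7 of the peak.
* **Initialisation.** Fits are deterministic (no random restarts):
  exponential fits start from a log-linear regression; the Bateman fit
  starts `k_leak` from the log-slope of the decay tail and `b_lER` from
  `AUC * k_clear`.
* **Optimiser.** Levenberg-Marquardt least squares (`minpack.lm::nlsLM`)
  with tight tolerances (`ftol = ptol = 1e-15` for the Bateman fit), all
  parameters bounded positive.
* **Out-of-range ratios** in the calibration are rejected, not clipped:
  silent clipping would flatten peak amplitudes. Callers may pre-clip
  explicitly.
* **Argmax ties** (inflection search) break toward the earliest time, and
  the two end samples — whose derivatives are one-sided — are excluded
  from the search and from the depletion regression.

## Derivatives, inflection and the depletion fit

The ER depletion is not exponential from the outset: TG reaches the SERCA
pumps cumulatively, so [Ca2+]_ER shows a flat phase, a sigmoidal onset and
only then a first-order decay. The time of maximal -d[Ca2+]_ER/dt (the
inflection point, `find_inflection()`) separates onset from decay;
`fit_depletion_rate()` regresses -d[Ca2+]_ER/dt on [Ca2+]_ER from there to
the trace end.

Derivatives are centred moving averages (default window 5 samples)
followed by central differences; end points use one-sided differences. Two
deliberate details:

* the regression uses the *smoothed* ER level as regressor, so the
  moving-average attenuation factor cancels between derivative and level;
  what remains is the central-difference bias `(k dt)^2 / 6` (&lt; 1% for
  all rates considered at 10-s sampling);
* the one-sided end samples are excluded from the regression.

The duration of a transient (in `transient_metrics()`) is defined as the
time from the stimulus until the trace first returns to within 5% of the
peak amplitude above baseline; the AUC integrates the baseline-subtracted
trace clipped at zero over that window (or the full support on request).
Both definitions are conventions of this package — reported decay spans in
the literature rarely state one — and are invariant under adding a
constant offset to the trace.

## What the synthetic generator emulates — and what it does not

`generate_experiment()` builds paired traces from a `ground_truth()`:

* cytosol: baseline (default 0.063 uM) plus a Bateman transient at each
  stimulus event, Gaussian noise (default SD 0.02 uM). The logistic onset
  can also be applied to the cytosolic transient but is **off by
  default**, so fixtures match the closed-form model exactly.
* ER: basal level (default 370 uM) flat before TG, then
  `b_er * exp(-k_depl * s(t))` where `s(t)` is the closed-form integral of
  a logistic activation (midpoint 60 s, width 15 s after TG) — flat, then
  sigmoidal onset, asymptotically exponential at `k_depl`. Noise SD
  defaults to 5 uM; this value is an assumption (recorded as such in the
  fixture manifest), since population summaries do not determine
  single-trace noise.
* clearance assay: linear SOCE rise (29.25 nM/s in the canonical fixture)
  from Ca2+ re-addition, exponential decay at `k_clear` after EGTA.
* sampling: 10 s for dual-sensor protocols, 3 s for FURA-2-alone, as in
  typical acquisitions; seeds are mandatory and the generator restores the
  session RNG state.

The canonical `fixture_suite()` uses the control / 500 uM puromycin /
1000 uM puromycin parameter triplets (`k_leak` 14.55e-3 / 21.03e-3 /
30.07e-3 s^-1, `b_lER` 2.40 / 2.38 / 0.62 uM, `k_depl` 6.28e-3 / 10.14e-3
/ 22.51e-3 s^-1, `k_clear` 28.34e-3 s^-1 throughout), with basal ER levels
scaled to 100% / 85% / 41% of control for the puromycin conditions.

What passing tests on this generator do **not** show about real data: no
cell-to-cell variability, no photobleaching or baseline drift, no
non-Gaussian sensor noise, no saturation of the indicator, and the
cytosolic onset convolution that real TG transients display is off by
default. Parameter recovery on fixtures is therefore a correctness check
of the estimators, not a claim about single-cell precision in an imaging
rig.

On recovery precision: a single noisy dual-sensor transient (10-s
sampling, 0.02 uM noise) determines `k_leak` to a standard error of
roughly 2-5% depending on amplitude; the test suite accordingly checks
noisy single-trace recovery against the fit's own standard error (3 SE)
and reserves fixed percentage bounds for medians over many replicates
(200-replicate median error &lt; 3% at `k_leak` = 21.03e-3, 3-s
sampling).

## Amplification vs attenuation

`phase_diagram()` sweeps `k_leak` (canonically 8e-3 to 35e-3 s^-1 in
3e-3 steps at `k_clear` = 28e-3 s^-1). With a constant luminal pool the
peak amplitude rises monotonically with `k_leak` while time-to-peak and
duration shrink; but a growing leak in a real cell drains the store, so
with a declining pool (linear 100% to 15% across the grid — the
intermediate schedule is a package choice, configurable per point) the
peak first rises, then falls: the amplification-to-attenuation switch. The
normalised shape depends only on `k_leak`, which is why *shortening* of
the transient is the robust indicator of an enhanced leak, while the
amplitude is ambiguous.

```{r phase, fig.width = 6, fig.height = 4}
pd <- phase_diagram(seq(8e-3, 35e-3, by = 3e-3), b_lER = 2.40,
                    k_clear = 28e-3, b_schedule = "declining")
plot(pd, main = "declining luminal pool: rise then fall")
head(pd$metrics[, c("k_leak", "b_lER", "t_peak", "peak")])
```

## Calibration

`ratio_to_concentration()` / `concentration_to_ratio()` implement the
standard ratiometric pair
`C = K (R - R_min)/(R_max - R)` and its algebraic inverse. K, R_min and
R_max are rig-specific; the package ships placeholder defaults (FURA-2
K = 0.22 uM, D1ER K = 60 uM, R_min = 0.5, R_max = 5) that are flagged as
non-physiological demonstration values and should always be replaced by an
instrument calibration. Raw four-channel fluorescence and background
subtraction are out of scope; inputs start at the ratio or concentration
level.

## Morphometry

`er_volume_fraction()` is deliberately minimal arithmetic on pre-measured
areas: area fraction `er_area/cell_area` and the stereological estimate
`volume fraction = (area fraction)^(3/2)`. Image segmentation itself is
out of scope. An area fraction of 0.61 gives a volume fraction of 0.476
(48% rounded); note that the power law makes the volume fraction the
smaller of the two for fractions below 1.

## Problem sizes and runtime

The shipped tests and the acceptance script run on deliberately small
problems: 600-s traces at 3- or 10-s sampling (61-201 samples), 200
replicate fits for the noisy-recovery medians, 30 replicates per noise
level for the noise-monotonicity check, and 50 random parameter sets for
the closed-form-vs-quadrature properties. These sizes were chosen so the
whole suite completes in seconds while keeping Monte-Carlo standard errors
well below the asserted tolerances.

## Known limitations

* One trace at a time: no hierarchical/population fitting; per-cell
  aggregation happens outside the package. Population means of per-cell
  rates and of per-cell time constants are not reciprocals of each other,
  so aggregated `k` and `tau` summaries should be formed from the same
  per-cell quantity.
* The Bateman model omits the cytosolic onset phase (cumulative SERCA
  inhibition); fitted `k_leak` absorbs some of that mismatch on real
  traces.
* `J_entry` (SOCE) is handled only empirically as a slope; no mechanistic
  SOCE/ORAI model.
* No luminal-buffering chemistry: `b_lER` is effective, not a measured
  free-luminal concentration.
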