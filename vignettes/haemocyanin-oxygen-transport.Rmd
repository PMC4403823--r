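---
title: "Methods: modelling haemocyanin oxygen transport in octopods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling haemocyanin oxygen transport in octopods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bluesat` analyses oxygen transport by the extracellular blood pigment
haemocyanin in octopod haemolymph. The pigment absorbs at 347 nm when
oxygenated, and its oxygen affinity is strongly pH dependent (the Bohr
effect), so the informative experiment is a diffusion-chamber run in which
pH is ramped downwards at constant oxygen partial pressure (PO2) while
absorbance is recorded. This vignette describes the models the package
implements, the choices behind their defaults, and what the synthetic-data
generator does and does not emulate.

## The saturation model

At each constant PO2, fractional pigment saturation as a function of
free-scale pH is described by an empirical five-parameter logistic (5PL):

$$S(\mathrm{pH}) = c + \frac{d - c}{\left(1 + e^{b\,(e_0 - \mathrm{pH})}\right)^{f}}$$

with lower asymptote $c$ (the residual saturation at low pH), upper
asymptote $d$, slope parameter $b > 0$ per pH unit, anchor $e_0$, and
asymmetry exponent $f > 0$ ($f = 1$ is a symmetric logistic with inflection
at $e_0$). The 5PL is an empirical description, not a mechanistic
(MWC-type) allosteric model; it is flexible enough for the asymmetric
curves haemocyanin produces while keeping every derived quantity (half
saturation, maximum slope) well defined.

Derived quantities:

* **pH50** — the root of $S(\mathrm{pH}) = 0.5$, found by a bracketing
  root-finder to 1e-8 pH. It is undefined when $c \ge 0.5$ (cold curves
  with high residual saturation) or $d \le 0.5$; such curves are reported
  as `undefined`, never silently extrapolated.
* **P50 at a stated pH** — each fixed-PO2 curve is half saturated at its
  pH50, so that PO2 *is* the P50 at that pH. Regressing log10(PO2) on pH50
  across the measured PO2 levels (21, 13, 4, 1 kPa) gives the Bohr line;
  evaluating it at a target pH (the alpha-stat venous pH) and
  exponentiating gives P50 in kPa. Evaluation outside the observed pH50
  range is flagged as extrapolation.
* **Bohr coefficient** — the slope of that same regression,
  $\Delta \log_{10} P_{50} / \Delta \mathrm{pH}$. Curves from several
  temperatures may be pooled; the pooled regression is unweighted, since
  there is no principled variance model for the individual pH50 estimates
  that would survive the bootstrap anyway.
* **Cooperativity of oxygenation-linked proton binding** — carrying
  capacity times the maximum slope $\max |dS/d\mathrm{pH}|$
  (mmol O2 L^-1 per pH unit), the pigment's capacity to release oxygen per
  unit acidification. The maximum of the analytic derivative is located
  numerically; for a symmetric logistic it equals $(d - c)\,b/4$.

## Fitting

`fit_5pl()` uses Levenberg--Marquardt least squares with box bounds
(`minpack.lm`), because 5PL fits are initialisation sensitive: five
deterministic starts are derived from the data quantiles (varying the
anchor, slope and asymmetry), a start that produces a singular Jacobian is
retried once from a slightly nudged position, and the converged fit with
the lowest residual sum of squares wins. Bounds are soft scientific
constraints, not tuning: $0 \le c \le 0.6$, $0.5 \le d \le 1.05$ (the
saturation scale is calibrated, so the upper asymptote must be near 1),
$b \in [0.5, 60]$, $f \in [0.1, 10]$, and the anchor within 2 pH units of
the observed window. Fits with $d - c < 0.05$ are rejected as degenerate.
At least 6 distinct pH points are required.

A note on identifiability: with $f$ free, the anchor $e_0$ trades off
against $f$ and is individually poorly determined even when the fitted
curve is excellent. All downstream quantities therefore use functionals of
the whole curve (pH50, maximum slope), which are stable; tests assert
recovery of those functionals, not of $e_0$.

Confidence intervals come from residual-resampling bootstrap (default
1,000 replicates, seeded): residuals are resampled with replacement, the
curve refit from the point estimate, and percentile intervals taken.
Intervals for P50 and the Bohr coefficient are formed jointly, replicate by
replicate, across the curves entering the regression, so the correlation
structure of the curve set is preserved.

## From raw traces to saturation

A chamber trace is calibrated in three steps:

1. **Maximum signal.** Pure-oxygen phases are recorded before and after
   the ramp; a least-squares line through their absorbances gives the
   maximum oxygenation signal at $t = 0$ and its linear drift (AU/h).
   Saturation is computed against the drift-corrected maximum
   $A_{max}(t)$.
2. **Minimum signal.** When the pigment deoxygenates fully under
   nitrogen, the median of the nitrogen phase is used. In the cold the
   minimum oxygenation signal stays elevated (incomplete deoxygenation),
   so the minimum is instead predicted from a reference wavelength of the
   first recorded spectrum via a linear model, with a 5% uncertainty band
   that is propagated into saturation bounds.
3. **pH scale.** Raw (NIST-calibrated) pH readings are converted to the
   free hydrogen ion scale by subtracting a constant offset, default
   0.136, appropriate for high-ionic-strength haemolymph; the free scale
   reads *lower*, hence the subtraction. An optional linear term removes
   instrumental optode drift.

Saturation is then $S(t) = (A(t) - A_{min}) / (A_{max}(t) - A_{min})$,
clipped to [0, 1] because noise can push calibrated values marginally
outside.

Oxygen carrying capacity comes from cyanide respirometry: a haemolymph
sample injected into a sealed chamber liberates its bound plus dissolved
oxygen as a concentration step; a seawater control contributes only
dissolved oxygen. Step sizes are differences of plateau medians (robust to
spikes) after removing a background-flux line fitted on the pre-injection
segment only (the post-injection segment may carry the step transient), so
the estimate is invariant to any drift common to both traces:
capacity = (step_sample - step_control) x chamber_vol / sample_vol.

## In-vivo projection

Haemolymph pH follows an **alpha-stat** pattern: venous pH falls linearly
with temperature, slope -0.0153 pH/degC, as for an imidazole-buffered
system. The default anchor is pH 7.42 at 0 degC; this anchor, with that
slope, reproduces the venous pH series 7.42 / 7.34 / 7.27 / 7.19 / 7.11 at
0/5/10/15/20 degC to two decimals, which a 10 degC anchor of exactly 7.27
does not (it gives 7.35 and 7.12 at 5 and 20 degC) — the 7.27 figure is
itself the rounded 10 degC value of this line (7.267). Arterial pH is a
constant 0.11 units above venous. Arterial PO2 is 13 kPa and venous PO2
4 kPa (resting) or 1 kPa (exercised), held constant across temperature.

**Dissolved oxygen** uses the Garcia--Gordon combined fit to the
Benson--Krause solubility data (micromol per kg at air saturation),
converted to per litre with the EOS-80 surface seawater density, and
scaled linearly with PO2 against an air PO2 of 21 kPa (the same reference
as the measured PO2 levels; a vapour-corrected air pressure would be the
alternative, but 21 kPa matches the chamber protocol). At 0 degC and
35 psu this gives 359 micromol/L, about 40% more than at 15 degC — the
physical basis for the large dissolved contribution to oxygen transport in
polar waters.

A **transport budget** combines both pools per litre of haemolymph:
arterial and venous saturations are read from the fitted curves (evaluated
at the in-vivo pH, linearly interpolated across log10 PO2; never
extrapolated beyond the measured 1--21 kPa), bound release is
capacity x (S_a - S_v), and dissolved release follows Henry's law. The
dissolved fraction of *total* content is computed as
sol / (sol + capacity), i.e. the air-saturated dissolved pool against the
full carrying capacity; this is the convention under which the published
per-species percentages (about 18.5% for the Antarctic species at 0 degC)
are recovered, whereas PO2-scaled arterial values are not.

## Circulation model

Metabolic demand scales allometrically, MO2 = 3.35 M^-0.27 (mmol O2 kg^-1
h^-1 with body mass in **grams** — with kilograms the function returns
rates far outside the observed octopod range), and with temperature by
Q10 = 2.12. Supply per circulation pass is the haemocyanin-bound oxygen
released over the 13 to 4 kPa arterial-venous transition (dissolved oxygen
can be added with a flag, off by default, since the comparison of interest
is pigment performance). The required whole-blood-volume turnover is
demand / supply / blood volume (5.2% v/w). Warming by 10 degC at constant
supply therefore demands exactly (Q10 - 1) x 100 = 112% more circulation;
any increase in pigment release with warming reduces that figure
proportionally.

## What the generator emulates — and what it does not

`simulate_chamber_experiment()` produces traces with the statistical
structure the processing chain assumes: oxygen/nitrogen calibration phases
bracketing a linear pH ramp, a linear drift of the maximum signal, a
constant raw-to-free pH scale offset (+0.136), and i.i.d. Gaussian noise
on absorbance and pH. The ground-truth pigment is a 5PL in pH whose half
saturation moves along a Bohr line in log10 PO2; temperature enters
through the P50 anchor (default 0.193 kPa/degC, the finite difference of
the published 0 and 10 degC P50 values of the Antarctic species) and
through the residual low-pH saturation, which may grow towards the cold to
emulate incomplete deoxygenation. The trace carries the
reference-wavelength scalar of its first spectrum, constructed equal to
the true minimum absorbance, so the identity model (0, 1) is its calibrated
minimum-signal predictor — a synthetic stand-in for the regression a
laboratory would fit across experiments.

Default study conditions: PO2 levels 21/13/4/1 kPa; 30 s sampling; a
1,800 s ramp (60 samples per curve); ramp pH from 8.1 (the NaOH-raised
start that ensures full initial oxygenation) down to 6.4. The ramp floor
follows the observation that half-saturation points of the high-PO2
curves sit near pH 6.5 and that measurements extend below pH 6.6; a ramp
stopping at 6.8 would leave those half-saturations outside the observed
window and make the high-PO2 curves pure shoulder data. Steepness defaults
to 8 per pH unit, the value implied by a cooperativity of ~3.2 mmol O2
L^-1 pH^-1 at a capacity of 1.58 mmol O2/L for a symmetric logistic.
Noise magnitudes (absorbance sd 0.005 AU, pH sd 0.01, drift -0.02 AU/h)
are fixture choices — no published values exist for them — selected so
that saturation noise is comparable to the scatter visible in replicated
curve fits.

The generator does **not** simulate the optics of the diffusion chamber,
CO2 equilibration chemistry, auto-fluorescence, or NaOH titration beyond
its effect (the ramp starts above pH 8). Its noise is i.i.d. Gaussian;
real optode and spectrometer noise is autocorrelated and
heteroscedastic. A single steepness is used at all temperatures, whereas
real cold curves are shallower. Passing recovery tests therefore
demonstrate that the processing and fitting chain is unbiased and precise
under the assumed error model — not that real traces meet that model.

## Numerical choices and degenerate inputs

* Root finding and maximisation use bracketing (`uniroot`, tolerance 1e-9)
  and golden-section (`optimize`, 1e-10) with analytic derivatives;
  both are verified against dense-grid brute force in the test suite
  (1,000 random 5PLs; agreement to 1e-4 pH and 1e-6 relative).
* Bohr regressions require at least two defined pH50 values and reject
  identical pH50s (degenerate line).
* The respirometry step must exceed 3x the baseline noise sd, otherwise
  the assay is reported as having no detectable step.
* All randomness flows from a single root seed through named substreams
  (`derive_seed(seed, label)`, exact in double precision and below 2^31),
  so simulation and bootstrap are jointly reproducible and two runs of the
  same configuration are byte identical.

## Problem sizes used by the test suite

The suite simulates 200 full four-level chamber studies (60 ramp points
per curve, saturation noise sd 0.02) for end-to-end recovery of P50 and
the Bohr coefficient within 5%, 500 replicates of the 33-point alpha-stat
regression (noise sd 0.072, the value giving R^2 around 0.75 on the
3 x 11 design), and 1,000-curve oracle sweeps; these sizes give stable
pass/fail behaviour while keeping a full run within a few minutes on one
core.

## Known limitations

* P50 at an alpha-stat venous pH above the observed pH50 range is an
  extrapolation of the Bohr line; at 0 degC this is the normal situation
  and the reported value carries that caveat (it is flagged).
* The 5PL lower asymptote is only identified when the ramp reaches the
  saturation floor; otherwise it absorbs noise and widens the P50
  interval.
* The dissolved-oxygen budget assumes seawater-like solubility for
  haemolymph and ignores CO2 chemistry, buffering, skin uptake and
  viscosity effects.
* The circulation model is a mass balance, not a haemodynamic model: no
  pressures, vessel mechanics or cardiac constraints.
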