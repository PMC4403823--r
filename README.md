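# bluesat

Analysis of blood oxygen transport by **haemocyanin**, the blue
copper-based respiratory pigment of octopods. Cephalopod haemocyanin is
extremely pH sensitive: acidification drives oxygen release (the Bohr
effect), and temperature shifts both oxygen affinity and blood pH (the
alpha-stat pattern). Whether an octopus can supply its tissues with oxygen
— especially near the freezing point of seawater, where pigment affinity is
high and unloading poor — therefore depends on the interplay of pigment
affinity (P50), Bohr coefficient, carrying capacity, dissolved oxygen and
circulation. `bluesat` implements that full analysis chain for
comparative respiratory physiologists, from raw diffusion-chamber traces
to circulatory supply–demand budgets, together with a seeded synthetic-data
generator so every stage is testable without laboratory data.

## What it computes

* **Trace processing** — calibration of 347 nm absorbance time series
  against drifting maximum and predicted/measured minimum oxygenation
  signals; conversion of raw pH to the free hydrogen ion scale
  (offset 0.136); carrying capacity from cyanide-respirometry steps.
* **Curve fitting** — five-parameter logistic pH–oxygen-saturation curves
  at constant PO2,
  `S(pH) = c + (d − c) / (1 + exp(b (e − pH)))^f`,
  with multi-start Levenberg–Marquardt and residual-bootstrap 95% CIs.
* **Binding parameters** — pH50 per curve; P50 at a stated pH and the Bohr
  coefficient `Δlog10 P50 / ΔpH` from the regression of log10 PO2 on pH50;
  cooperativity of oxygenation-linked proton binding
  (capacity × max |dS/dpH|, mmol O2 L⁻¹ pH⁻¹); ΔP50/°C.
* **In-vivo projection** — alpha-stat venous pH (−0.0153 pH/°C, 7.42 at
  0 °C), arterial pH +0.11, arterial/venous saturations at 13 / 4 / 1 kPa,
  seawater O2 solubility (Garcia–Gordon fit + EOS-80 density) and the
  bound + dissolved oxygen delivered per litre of haemolymph.
* **Circulation model** — allometric metabolic rate (3.35 M⁻⁰·²⁷, M in g),
  Q10 scaling (2.12), and the whole-blood-volume turnover (blood volume
  5.2% v/w) required to match demand with measured pigment supply.

## Worked example

Simulate a four-PO2 diffusion-chamber study from a known Antarctic-like
pigment (P50 2.34 kPa at pH 7.27 and 10 °C, Bohr −1.22, capacity
1.58 mmol O2/L), process and fit it, and project oxygen delivery for an
exercised octopus:

```r
library(bluesat)

pigment <- ground_truth_pigment()   # Antarctic-like anchors
run <- simulate_chamber_experiment(pigment, chamber_protocol(temperature = 10),
                                   noise_model(abs_sd = 0.005, ph_sd = 0.005,
                                               seed = 42))
curves <- process_chamber_run(run, n_boot = 200, seed = 42)
binding_params(curves, capacity = 1.58,
               venous_ph = venous_ph(alpha_stat_model(), 10))
#> Binding parameters at 10 degC
#>   P50 at pH 7.267 : 2.369 kPa
#>   Bohr coefficient: -1.214
#>   Cooperativity   : 3.152 mmol O2 L-1 pH-1

transport_budget(curves, capacity = 1.58,
                 in_vivo_conditions(temperature = 10, venous_po2 = 1))
#> Transport budget at 10 degC (PO2 13 -> 1 kPa, pH 7.38 -> 7.27)
#>   saturation        : arterial 0.996, venous 0.079
#>   bound O2 released : 1.448 mmol/L (92.1% of bound)
#>   dissolved released: 0.161 mmol/L
#>   total released    : 1.609 mmol/L (10.0% dissolved)
#>   dissolved share of total content: 15.1%
```

The fitted P50 (2.369 kPa) and Bohr coefficient (−1.214) recover the
generator's truth (2.34, −1.22) within about 1%; the budget says that at
10 °C this pigment would hand over 92% of its bound oxygen between 13 and
1 kPa, with dissolved oxygen contributing a further 10% of the total
release. Converting capacity to pigment concentration:

```r
hc_concentration(1.58)   # 70 O2 binding sites, 3.5 MDa
#> [1] 79.0                # g/L = mg/ml
```

A whole multi-temperature study (simulation, fits, budgets at venous PO2 4
and 1 kPa, circulation comparison) runs from one seeded configuration:

```r
cfg <- system.file("extdata", "example_study.yaml", package = "bluesat")
report <- run_study(cfg)
write_report(report, "study_out")   # CSV tables + report.json
```

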