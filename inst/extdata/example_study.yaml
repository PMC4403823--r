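# Minimal synthetic study: one Antarctic-like pigment at 0 and 10 degC.
# All values are simulation ground truth, not measurements.
seed: 42
n_boot: 200
species:
- name: antarctic_synthetic
  capacity: 1.58          # mmol O2 / L haemolymph
  temperatures: [0.0, 10.0]
  pigment:
    p50_ref: 2.34         # kPa at ph_ref and ref_temp
    ph_ref: 7.27
    bohr_slope: -1.22
    steepness: 8.0
    asymmetry: 1.0
    temp_coeff: 0.193     # kPa P50 per degC
    ref_temp: 10.0
noise:
  abs_sd: 0.005           # AU
  ph_sd: 0.005
alpha_stat:
  slope: -0.0153          # pH per degC
  anchor_ph: 7.42
  anchor_temp: 0.0
venous_po2: [4.0, 1.0]    # kPa: resting and exercised
circulation:
  mo2_ref: 0.63           # mmol O2 / kg / h at t_ref
  t_ref: 0.0
  q10: 2.12
  blood_volume_frac: 0.052
  include_dissolved: false
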