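# Severe renal impairment (creatinine CL 11-30 mL/min), 1000 mg IV / 30 min
# (study arm 9). GFR defaults to the band midpoint, 20.5 mL/min.
name: severe_ckd_1000mg
population:
  n_subjects: 100
  n_observed: 5
  age: [27.4, 62.6]
  weight: [64.6, 101.4]
  n_females: 0
  disease: severe_ckd
regimen:
  dose_mg: 1000
  infusion_min: 30
simulation:
  horizon_h: 48
  dt_h: 0.1
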