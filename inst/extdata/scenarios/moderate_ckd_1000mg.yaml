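# Moderate renal impairment (creatinine CL 31-60 mL/min), 1000 mg IV / 30 min
# (study arm 8). GFR defaults to the band midpoint, 45.5 mL/min.
name: moderate_ckd_1000mg
population:
  n_subjects: 100
  n_observed: 5
  age: [31.4, 60.6]
  weight: [57.5, 74.4]
  n_females: 0
  disease: moderate_ckd
regimen:
  dose_mg: 1000
  infusion_min: 30
simulation:
  horizon_h: 48
  dt_h: 0.1
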