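# Healthy adults, dose-ranging arm 62.5-2000 mg IV over 30 min (study arm 2).
name: healthy_02_doserange
population:
  n_subjects: 100
  n_observed: 24
  age: [28.5, 33.5]
  weight: [84.6, 93.2]
  n_females: 0
  disease: healthy
regimen:
  dose_mg: [62.5, 125, 250, 500, 1000, 2000]
  infusion_min: 30
simulation:
  horizon_h: 12
  dt_h: 0.05
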