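# Healthy adults, 250-2000 mg IV over 30 min (study arm 5).
name: healthy_05_doserange
population:
  n_subjects: 100
  n_observed: 31
  age: [20, 44]
  weight: [70.6, 79]
  n_females: 0
  disease: healthy
regimen:
  dose_mg: [250, 500, 1000, 2000]
  infusion_min: 30
simulation:
  horizon_h: 12
  dt_h: 0.05
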