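# Healthy adults, 2000 mg IV over 30 min (study arm 4).
name: healthy_04_2000mg
population:
  n_subjects: 100
  n_observed: 6
  age: [23, 43]
  weight: [72.2, 110]
  n_females: 0
  disease: healthy
regimen:
  dose_mg: 2000
  infusion_min: 30
simulation:
  horizon_h: 12
  dt_h: 0.05
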