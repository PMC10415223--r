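# Healthy adults over a wide age span, 1000 mg IV over 30 min (study arm 6).
name: healthy_06_1000mg
population:
  n_subjects: 100
  n_observed: 48
  age: [20, 81]
  weight: [54, 86]
  n_females: 24
  disease: healthy
regimen:
  dose_mg: 1000
  infusion_min: 30
simulation:
  horizon_h: 12
  dt_h: 0.05
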