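# Healthy adults, single 1000 mg IV infusion over 30 min (study arm 1).
name: healthy_01_1000mg
population:
  n_subjects: 100
  n_observed: 12  # subjects in the clinical study
  age: [25.2, 27.8]
  weight: [66.5, 80.3]
  n_females: 6
  disease: healthy
regimen:
  dose_mg: 1000
  infusion_min: 30
simulation:
  horizon_h: 12
  dt_h: 0.05
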