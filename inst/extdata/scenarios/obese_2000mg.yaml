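# Obese adults (BMI > 30), 2000 mg IV over 30 min (study arm 10).
name: obese_2000mg
population:
  n_subjects: 100
  n_observed: 10
  age: [31, 74]
  weight: [106.8, 163.2]
  n_females: 5
  disease: obese
regimen:
  dose_mg: 2000
  infusion_min: 30
simulation:
  horizon_h: 12
  dt_h: 0.05
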