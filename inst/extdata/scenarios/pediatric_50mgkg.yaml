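# Pediatric patients (2 months - 18 years), 50 mg/kg IV over 30 min (arm 7).
name: pediatric_50mgkg
population:
  n_subjects: 100
  n_observed: 37
  age: [0.175, 16.4]
  weight: [3.5, 75]
  n_females: 16
  disease: pediatric
regimen:
  dose_mg_per_kg: 50
  infusion_min: 30
simulation:
  horizon_h: 12
  dt_h: 0.05
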