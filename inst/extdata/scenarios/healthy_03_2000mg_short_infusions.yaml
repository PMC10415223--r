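# Healthy adults, 2000 mg IV over 3/5/10/15 min (study arm 3).
# The study did not report weights; a typical adult range is assumed.
name: healthy_03_2000mg_short_infusions
population:
  n_subjects: 100
  n_observed: 16
  age: [21, 38]
  weight: [60, 90]
  n_females: 0
  disease: healthy
regimen:
  dose_mg: 2000
  infusion_min: [3, 5, 10, 15]
simulation:
  horizon_h: 12
  dt_h: 0.05
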