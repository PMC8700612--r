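# Dose-algorithm configuration; any key may be omitted and defaults apply.
# This example uses the revised branch threshold.
weight_threshold_kg: 82
floor_policy:
  crt_min: [0.0, 1.5]
  floor_MBq: [100, 150]
sex_coding:
  male: 1
  female: 0
half_life_min: 360.4
time_rounding_min: 5
effective_dose_coef_mSv_per_MBq: 0.0062
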