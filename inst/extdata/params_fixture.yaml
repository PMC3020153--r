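probabilities:
  p_icu_fullcode_severely_ill:
    point: 0.6902
    low: 0.55
    high: 0.85
    provenance: median
  p_icu_fullcode_moderately_ill:
    point: 0.2977
    low: 0.15
    high: 0.45
    provenance: median
  p_icu_dni_severely_ill:
    point: 0.4017
    low: 0.2
    high: 0.6
    provenance: expert
  p_icu_dni_moderately_ill:
    point: 0.1537
    low: 0.05
    high: 0.3
    provenance: expert
  p_ett_severely_ill:
    point: 0.6875
    low: 0.5
    high: 0.9
    provenance: median
  p_ett_moderately_ill:
    point: 0.3072
    low: 0.15
    high: 0.5
    provenance: median
  p_nimv_ward_fullcode:
    point: 0.462
    low: 0.25
    high: 0.65
    provenance: median
  p_nimv_ward_dni:
    point: 0.5553
    low: 0.2
    high: 0.8
    provenance: expert
  p_death_ett:
    point: 0.2217
    low: 0.12
    high: 0.35
    provenance: pooled
  p_ett_complication:
    point: 0.2434
    low: 0.1
    high: 0.65
    provenance: median
  p_death_nimv:
    point: 0.1474
    low: 0.08
    high: 0.25
    provenance: pooled
  p_nimv_failure_severely_ill:
    point: 0.2942
    low: 0.15
    high: 0.45
    provenance: pooled
  p_nimv_failure_moderately_ill:
    point: 0.2022
    low: 0.1
    high: 0.35
    provenance: pooled
  p_death_medical_severely_ill:
    point: 0.4469
    low: 0.3
    high: 0.6
    provenance: median
  p_death_medical_moderately_ill:
    point: 0.1219
    low: 0.06
    high: 0.2
    provenance: pooled
  p_death_failed_nimv_medical:
    point: 0.7499
    low: 0.55
    high: 0.9
    provenance: expert
  p_cmo_after_failed_ventilation:
    point: 0.3546
    low: 0.15
    high: 0.55
    provenance: expert
  p_survival_cmo:
    point: 0.103
    low: 0.02
    high: 0.25
    provenance: expert
  p_longterm_ecf:
    point: 0.3971
    low: 0.2
    high: 0.6
    provenance: median
  p_shortterm_ecf:
    point: 0.2542
    low: 0.1
    high: 0.4
    provenance: median
utilities:
  u_copd_mild:
    point: 0.8722
    low: 0.75
    high: 0.95
    provenance: pooled
  u_copd_moderate:
    point: 0.7272
    low: 0.6
    high: 0.85
    provenance: pooled
  u_copd_severe:
    point: 0.6055
    low: 0.45
    high: 0.75
    provenance: pooled
tto:
- state: ett_complication
  time_traded: 0.0
  units: months
- state: long_term_ecf
  time_traded: 0.0
  units: months
survival:
  copd_mild:
    horizon: 4.0
    survival: 0.782
  copd_moderate:
    horizon: 4.0
    survival: 0.5916
  copd_severe:
    horizon: 4.0
    survival: 0.3476
  ecf:
    horizon: 1.0
    survival: 0.6699
metadata:
  model: copd-advance-directive
  version: 1
  seed: 1
  note: synthetic stand-in parameter set (generated fixture); every value is a placeholder,
    not a published estimate
defaults:
  severity: severe
  exacerbation_mix: 0.5
  complication_months: 1.0
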