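name: ahon_style
quarter_rule: from_enrollment_date
pseudonym_scheme: pc3_birthyear_sex
claims_filter: all
contact_codes_filter: ~
dedup_window_days: 0
include_pharmacy_prescriptions: no
episode_mode: recorded
lookback_years: 2
contact_free_interval_days:
  U71: 28.0
  R05: 90.0
contact_free_interval_default: 90.0
chronic_codes:
- T90
- K86
collision_policy: drop
salt: ahon_style
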