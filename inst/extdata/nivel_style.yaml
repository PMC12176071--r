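name: nivel_style
quarter_rule: from_capitation_imputed
pseudonym_scheme: ssn
claims_filter:
- '12001'
- '12002'
- '12003'
- '12010'
- '12011'
- '12004'
- '12024'
- '13012'
contact_codes_filter: ~
dedup_window_days: 8
include_pharmacy_prescriptions: yes
episode_mode: construct
lookback_years: 2
contact_free_interval_days:
  U71: 28.0
  R05: 90.0
contact_free_interval_default: 90.0
chronic_codes:
- T90
- K86
collision_policy: drop
salt: nivel_style
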