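# Example simulation configuration for `fasss.R simulate`.
# Fields mirror cohort_params() / reader_error_params(); omitted fields
# keep the package defaults.
cohort:
  n_patients: 30
  accrual_rate: 2.0
  p_regress: 0.05
  seed: 20260101
reader1:
  sensitivity: 0.92
  false_positive_rate: 0.004
  p_size_misgrade: 0.10
  seed_offset: 1
reader2:
  sensitivity: 0.90
  false_positive_rate: 0.005
  p_size_misgrade: 0.12
  seed_offset: 2
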