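# Demo synthetic-cohort configuration: a mid-sized cohort with availability
# bias planted on one group's medication records and observation periods
# (odds multiplier exp(-0.7) ~= 0.497).
n_patients: 20000
race_probs:
  Asian: 0.10
  Black or African: 0.25
  White: 0.40
  Unknown: 0.25
ethnicity_probs:
  Hispanic or Latino: 0.20
  Non-Hispanic or non-Latino: 0.60
  Unknown: 0.20
group_multipliers:
  Black or African:
    medication: 0.4966
    observation_period: 0.4966
seed: 20240601
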