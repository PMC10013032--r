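schema_version: 1
model:
  m: 1
  'n': 1
  p: 1
  initial_thresholds: 3.0
  processing_delays: 1
  effector_delays: 1
  routing:
    '*': 1
  component_policy:
    '*': 1
  effector_policy:
    '*': 1
  adaptation:
    rule: none
stimuli:
  explicit:
  - tick: 0
    modality: pin_prick
    strength: 5.0
run:
  ticks: 15
  seed: 1
outputs:
  trace: trace.ndjson
  summary: summary.tsv
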