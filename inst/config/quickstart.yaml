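# Quickstart pipeline: a small high-separation synthetic cohort with
# compact nodes and coarser slides, sized so a full leave-one-out run
# completes in a few minutes on one CPU.
cohort:
  n_participants: 6
  trials_per_activity: {chair: 3, stairs_up: 2, stairs_down: 2, walking: 2}
  sample_rate_hz: 100
  separation: 2.5
  noise_sd: 0.05
  participant_sd: 0.10
windows:
  "1": {window_ms: 200, slide_ms: 50}
  "2": {window_ms: 100, slide_ms: 20}
  "3": {window_ms: 40, slide_ms: 20}
train:
  learning_rate: 0.001
  max_epochs: 8
  patience: 2
  dropout_rate: 0.3
  batch_size: 64
  filters: [8, 16, 32]
  dense_units: 32
routing: truth
seed: 20260930
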