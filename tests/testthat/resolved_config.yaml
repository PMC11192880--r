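seed: 1.0
paths:
  data: '.'
  models: '.'
  outputs: '.'
loss:
  family: masked-lz
  z: 2.0
train:
  steps: 300.0
  lr: 0.0001
  batch_size: 1.0
  channels: 12.0
  peak_radius: 1.0
adapt:
  threshold: 0.5
  iterations: 1000.0
  batch_size: 1.0
  freeze_norm_stats: yes
  lr: 0.0001
pyramid:
  scales: '1'
  confidence_threshold: 0.5
  cosine_threshold: 0.95
sigma:
  preset: mouse
features:
  arena: ~
gait:
  cutoff: 3.0
  order: 2.0
  trim_seconds: 2.0
  back_keypoint: back
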