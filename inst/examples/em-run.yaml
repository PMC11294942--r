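synthetic:
  n_samples: 5
  size: [64, 64]
  n_nodules: [1, 2]
  nodule_radius: [4, 7]
preprocess:
  - stage: wiener
    window: 3
segmenter:
  method: em
  k: 3
evaluation:
  metrics: [dice, iou, pri, voi, gce]
seed: 7
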