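{
  "source": "synthetic",
  "synth": {"fs": 360, "n_per_class": 30, "noise_sd": 0.05},
  "egwo": {"num_wolves": 10, "max_iter": 10, "init_k": 10},
  "train": {"epochs": 20}
}
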