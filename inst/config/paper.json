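{
  "source": "synthetic",
  "synth": {"fs": 360, "n_per_class": 100, "noise_sd": 0.05},
  "window_s": 1.0,
  "stride_s": 1.0,
  "egwo": {"num_wolves": 30, "max_iter": 100, "init_k": 30, "knn_k": 5, "cv_folds": 5},
  "train": {"learning_rate": 0.01, "batch_size": 100, "epochs": 30, "l2": 0.001,
            "dropout": 0.2, "hidden_size": 50, "early_stop_patience": 6}
}
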