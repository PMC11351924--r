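{
  "intercept": 0.190628340604796,
  "coef": [1.26545913035787, 1.49444941955131],
  "center": [1.01278734669969, 4.50049183494267],
  "scale": [0.013631523008138, 1.2126782808854],
  "feature_names": ["mean_tortuosity", "mean_width"],
  "n": 200,
  "seed": 2024,
  "train_accuracy": 1
}
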