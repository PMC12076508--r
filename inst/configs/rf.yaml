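# desk-scale random forest defaults (seconds on one CPU)
family: rf
n_estimators: 300
min_samples_leaf: 2
max_features: sqrt
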