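# study-scale random forest settings: 1800 trees at depth 100 covers the
# existence / multiclass / R-vs-S tasks; the 0-vs-1 and sign tasks used
# 1200 trees (depths 420 / 100 / 420) -- override per task as needed
family: rf
n_estimators: 1800
max_depth: 100
min_samples_leaf: 2
max_features: sqrt
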