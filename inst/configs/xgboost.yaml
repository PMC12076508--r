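# desk-scale gradient boosting defaults
family: gbdt
n_estimators: 100
max_depth: 6
eta: 0.3
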