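# study-scale XGBoost settings: max_depth 20 with default boosting
# parameters; the single-center sign task used eta 0.13 and the all-
# molecule sign task eta 0.1 with the error eval metric
family: gbdt
n_estimators: 100
max_depth: 20
eta: 0.3
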