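# study-scale network training: at least 10000 epochs until convergence
family: ann
hidden: [500, 200]
dropout: 0.05
lr: 0.001
optimizer: adam
epochs: 10000
patience: 200
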