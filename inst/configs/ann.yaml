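# desk-scale feed-forward network: same architecture as the study
# (input -> 500 -> 200 -> softmax, dropout 0.05), short epoch budget
family: ann
hidden: [500, 200]
dropout: 0.05
lr: 0.001
optimizer: adam
epochs: 200
patience: 25
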