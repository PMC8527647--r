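# Example oracle spec for the CLI: a random separable landscape.
# fastseqprop design --method fast_seqprop --oracle linear_toy.yaml --length 8 ...
kind: linear
n_pos: 8
seed: 3
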